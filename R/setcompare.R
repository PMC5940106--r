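#' Unique gene annotations among loci of one direction
#'
#' Multiple promoters may annotate to the same gene; downstream set
#' comparisons work at the gene level. Case-sensitive uniqueness; a promoter
#' lacking a gene annotation is kept under its own promoter id so it is never
#' silently merged with other unannotated promoters.
#'
#' @param results a `lifespan_scan` (or any data.frame with `locus`, `gene`,
#'   `direction` columns).
#' @param direction which direction class to keep (`"positive"`,
#'   `"negative"`, ...); `NULL` keeps all rows.
#' @return character vector: the unique gene-name set.
#' @export
dedup_genes <- function(results, direction = NULL) {
  df <- as.data.frame(results)
  if (!is.null(direction)) df <- df[df$direction %in% direction, , drop = FALSE]
  if (nrow(df) == 0L) return(character())
  g <- ifelse(is.na(df$gene) | !nzchar(df$gene), df$locus, df$gene)
  unique(g)
}

#' Overlap accounting between two gene sets
#'
#' @param setA,setB character vectors (duplicates removed).
#' @param labels length-2 character vector naming the sets.
#' @return a `gene_set_comparison`: list with `label_a`, `label_b`, `size_a`,
#'   `size_b`, `shared`, `a_only`, `b_only`.
#' @export
overlap <- function(setA, setB, labels = c("A", "B")) {
  setA <- unique(setA); setB <- unique(setB)
  shared <- length(intersect(setA, setB))
  set_comparison(length(setA), length(setB), shared, labels)
}

#' Overlap accounting from published sizes
#'
#' When only the set sizes and the shared count are known (e.g. counts
#' printed in a report), the set-specific counts follow by arithmetic:
#' `a_only = size_a - shared`, `b_only = size_b - shared`.
#'
#' @param size_a,size_b set sizes.
#' @param shared size of the intersection.
#' @param labels length-2 character vector naming the sets.
#' @return a `gene_set_comparison`.
#' @export
set_comparison <- function(size_a, size_b, shared, labels = c("A", "B")) {
  stopifnot(shared >= 0, shared <= size_a, shared <= size_b)
  structure(list(label_a = labels[1L], label_b = labels[2L],
                 size_a = as.integer(size_a), size_b = as.integer(size_b),
                 shared = as.integer(shared),
                 a_only = as.integer(size_a - shared),
                 b_only = as.integer(size_b - shared)),
            class = "gene_set_comparison")
}

#' @export
print.gene_set_comparison <- function(x, ...) {
  cat(sprintf("Gene set overlap: %s (n=%d) vs %s (n=%d)\n",
              x$label_a, x$size_a, x$label_b, x$size_b))
  cat(sprintf("  shared %d | %s-only %d | %s-only %d\n",
              x$shared, x$label_a, x$a_only, x$label_b, x$b_only))
  invisible(x)
}

#' Direction-skew exact binomial test
#'
#' Tests whether significant loci split evenly between positive and negative
#' slopes. Under a direction-unbiased pipeline the null is Binomial(n, 1/2);
#' the two-sided p-value sums the probability of every outcome at most as
#' likely as the observed one (minimum-likelihood ordering, the standard
#' exact two-sided definition, via [stats::binom.test()]).
#'
#' @param n_pos,n_neg counts of positively and negatively correlated loci.
#' @return list with `prop_pos` (fraction positive), `p` (exact two-sided
#'   p-value), `n` (total).
#' @export
#' @examples
#' skew_test(930, 57)   # the ~95% positive skew regime: p << 0.001
skew_test <- function(n_pos, n_neg) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  n <- n_pos + n_neg
  if (n < 1L) stop("need at least one significant locus")
  bt <- stats::binom.test(n_pos, n, p = 0.5, alternative = "two.sided")
  list(prop_pos = n_pos / n, p = min(1, bt$p.value), n = n)
}

#' Compare two scan results: dedup, overlap, and skew
#'
#' Gene-level comparison of two per-locus scans (e.g. a primate-only subset
#' vs the full mammal set): per-direction unique-gene sets, their overlap,
#' and the direction-skew test within each scan.
#'
#' @param resultsA,resultsB `lifespan_scan` objects or results data.frames.
#' @param labels length-2 character vector naming the scans.
#' @return list with per-direction `gene_set_comparison`s (`positive`,
#'   `negative`) and per-scan skew tests (`skew_a`, `skew_b`).
#' @export
compare_scans <- function(resultsA, resultsB, labels = c("A", "B")) {
  res <- list()
  for (dir in c("positive", "negative")) {
    res[[dir]] <- overlap(dedup_genes(resultsA, dir),
                          dedup_genes(resultsB, dir), labels)
  }
  dA <- table(factor(as.data.frame(resultsA)$direction,
                     levels = c("positive", "negative")))
  dB <- table(factor(as.data.frame(resultsB)$direction,
                     levels = c("positive", "negative")))
  res$skew_a <- skew_test(dA[["positive"]], dA[["negative"]])
  res$skew_b <- skew_test(dB[["positive"]], dB[["negative"]])
  res$labels <- labels
  res
}
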