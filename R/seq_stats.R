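#' Count CpG dinucleotides
#'
#' Number of positions i with `seq[i] == "C"` and `seq[i+1] == "G"` (5'->3').
#' Because the two letters differ, occurrences cannot overlap, so this equals
#' the plain non-overlapping match count. Any pair involving `N` is not a CpG.
#' Input must be gap-free; strip alignment gaps first (see
#' [assemble_locus()]).
#'
#' @param seq character vector of gap-free sequences (case-insensitive).
#' @return integer vector of CpG counts.
#' @export
#' @examples
#' cpg_count(c("ACGT", "CGCG", "CCGG", "AAAA"))  # 1 2 1 0
cpg_count <- function(seq) {
  if (any(grepl("-", seq, fixed = TRUE)))
    stop("gapped sequence: remove alignment gaps before counting CpGs")
  seq <- toupper(seq)
  hits <- gregexpr("CG", seq, fixed = TRUE)
  vapply(hits, function(h) if (h[1L] == -1L) 0L else length(h), 0L)
}

#' CpG density of a sequence
#'
#' CpG dinucleotide count divided by sequence length, in sites per
#' nucleotide. This is the per-nt convention used throughout the package;
#' a fixed positive rescaling of the predictor (per-nt, per-kb, or the raw
#' count when match lengths are near-constant) leaves PGLS slope signs and
#' p-values unchanged, so the choice of unit is cosmetic. The raw count is
#' also carried through the locus tables. Bounded in `[0, 0.5]`.
#'
#' @param seq character vector of gap-free sequences, each of length >= 2.
#' @return numeric vector of densities.
#' @export
cpg_density <- function(seq) {
  n <- nchar(seq)
  if (any(n < 2L)) stop("sequence shorter than 2 nt: CpG density undefined")
  cpg_count(seq) / n
}

#' GC content of a sequence
#'
#' Percentage of G+C among unambiguous bases: `N` is excluded from the
#' denominator. An all-N sequence has no defined GC content.
#'
#' @param seq character vector of gap-free sequences, each of length >= 1.
#' @return numeric vector, percent in `[0, 100]`.
#' @export
gc_content <- function(seq) {
  n <- nchar(seq)
  if (any(n < 1L)) stop("empty sequence: GC content undefined")
  if (any(grepl("-", seq, fixed = TRUE)))
    stop("gapped sequence: remove alignment gaps before computing GC content")
  seq <- toupper(seq)
  gc <- nchar(gsub("[^GC]", "", seq))
  nn <- nchar(gsub("[^N]", "", seq))
  denom <- n - nn
  if (any(denom == 0L)) stop("all-N sequence: GC content undefined")
  100 * gc / denom
}

#' Full composition summary of sequences
#'
#' @param seq character vector of gap-free sequences.
#' @return data.frame with columns `length`, `cpg_count`, `cpg_density`,
#'   `gc_content`.
#' @export
seq_composition <- function(seq) {
  data.frame(length = nchar(seq),
             cpg_count = cpg_count(seq),
             cpg_density = cpg_density(seq),
             gc_content = gc_content(seq))
}
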