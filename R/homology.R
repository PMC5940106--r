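#' Keep the single best hit per promoter per species
#'
#' Reduces a raw hit table to exactly one row per (query promoter, species)
#' pair. Selection is by maximum bitscore; ties broken by minimum e-value,
#' then maximum alignment length, then lexicographically smallest subject
#' accession, then smallest subject start. The chain is total, so the result
#' is deterministic and invariant to input row order.
#'
#' @param hits data.frame of hits as from [read_blast_tab()] (possibly
#'   concatenated over species files).
#' @return data.frame with one row per (query_id, species), ordered by
#'   query_id then species.
#' @export
best_hit_per_species <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query_id, hits$species,
               -hits$bitscore, hits$evalue, -hits$aln_len,
               hits$subject_acc, pmin(hits$s_start, hits$s_end),
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  keep <- !duplicated(hits[, c("query_id", "species")])
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter hits by percent identity
#'
#' A hit survives iff `pct_identity >= threshold`. The base analysis keeps
#' matches at the 70% tier; 90/95/99% tiers measure conservation depth.
#'
#' @param hits data.frame of hits.
#' @param threshold percent identity threshold in (0, 100].
#' @return the surviving rows.
#' @export
filter_identity <- function(hits, threshold = 70) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 100)
    stop("identity threshold must be a single value in (0, 100]")
  out <- hits[hits$pct_identity >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cumulative identity-tier counts
#'
#' Counts hits meeting each identity tier. Tiers are cumulative: a 99%-identity
#' hit counts in all four tiers, so counts are monotone nonincreasing.
#'
#' @param hits data.frame of hits.
#' @param tiers numeric vector of thresholds (default `c(70, 90, 95, 99)`).
#' @return named integer vector of counts, one per tier.
#' @export
tier_counts <- function(hits, tiers = c(70, 90, 95, 99)) {
  stats::setNames(
    vapply(tiers, function(t) sum(hits$pct_identity >= t), 0L),
    paste0("ge", tiers))
}

#' Assemble a per-locus multi-species table
#'
#' Builds the per-promoter species table from best-per-species,
#' identity-filtered hits: the stored sequence is the subject (species-side)
#' aligned sequence with gap characters removed — the species' own promoter
#' composition is the evolving trait of interest — and CpG/GC statistics are
#' computed on it. Species on the exclusion list (manual outlier handling,
#' e.g. a single extreme-lifespan pinniped) are dropped before anything else.
#'
#' @param promoter_id the query promoter id.
#' @param hits rows of the hit table for this promoter (one per species).
#' @param gene gene annotation for the promoter (`NA` if unknown).
#' @param exclude character vector of species to drop.
#' @return a `locus_table`: data.frame with columns `species`, `sequence`,
#'   `match_len`, `pct_identity`, `cpg_count`, `cpg_density`, `gc_content`;
#'   attributes `promoter_id` and `gene`.
#' @export
assemble_locus <- function(promoter_id, hits, gene = NA_character_,
                           exclude = character()) {
  if (nrow(hits) > 0L) {
    stopifnot(all(hits$query_id == promoter_id))
    if (anyDuplicated(hits$species))
      stop("multiple hits per species for ", promoter_id,
           ": run best_hit_per_species() first")
  }
  if (length(exclude))
    hits <- hits[!hits$species %in% normalize_species(exclude), , drop = FALSE]
  seqs <- gsub("-", "", toupper(hits$s_seq), fixed = TRUE)
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    warning("dropping species with all-gap subject sequence at ", promoter_id,
            ": ", paste(hits$species[empty], collapse = ", "))
    hits <- hits[!empty, , drop = FALSE]
    seqs <- seqs[!empty]
  }
  out <- data.frame(
    species = hits$species,
    sequence = seqs,
    match_len = nchar(seqs),
    pct_identity = hits$pct_identity,
    stringsAsFactors = FALSE)
  if (nrow(out)) {
    out$cpg_count <- cpg_count(out$sequence)
    out$cpg_density <- out$cpg_count / out$match_len
    out$gc_content <- gc_content(out$sequence)
  } else {
    out$cpg_count <- integer(); out$cpg_density <- numeric()
    out$gc_content <- numeric()
  }
  rownames(out) <- NULL
  attr(out, "promoter_id") <- promoter_id
  attr(out, "gene") <- gene
  class(out) <- c("locus_table", "data.frame")
  out
}

#' Per-group mean match length
#'
#' Mean ungapped match length over all (locus, species) entries, within named
#' species groups (e.g. primates vs non-primate mammals). Species missing
#' from the partition are ignored; an empty group yields `NA`.
#'
#' @param loci list of `locus_table`s (see [assemble_locus()]).
#' @param species_partition named character vector: species -> group label.
#' @return named numeric vector of group means (NA for empty groups).
#' @export
match_length_summary <- function(loci, species_partition) {
  stopifnot(!is.null(names(species_partition)))
  names(species_partition) <- normalize_species(names(species_partition))
  groups <- unique(unname(species_partition))
  sp <- unlist(lapply(loci, `[[`, "species"), use.names = FALSE)
  len <- unlist(lapply(loci, `[[`, "match_len"), use.names = FALSE)
  grp <- species_partition[sp]
  out <- vapply(groups, function(g) {
    v <- len[!is.na(grp) & grp == g]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  names(out) <- groups
  out
}
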