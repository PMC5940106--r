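#' Normalize a species name
#'
#' Trims surrounding whitespace and collapses any internal run of whitespace
#' or underscores to a single underscore. Case is preserved. Used to reconcile
#' species labels across hit tables, trait tables and tree tip labels, where
#' the same species is variously written `"Homo sapiens"` or `"Homo_sapiens"`.
#' Idempotent: `normalize_species(normalize_species(x)) == normalize_species(x)`.
#'
#' @param x character vector of species names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_species(c("Homo sapiens", "  Mus   musculus "))
normalize_species <- function(x) {
  x <- trimws(x)
  gsub("[[:space:]_]+", "_", x)
}

#' Column names of the homology hit dialect
#'
#' The 14 tab-separated columns emitted by a megablast search configured to
#' report the aligned sequences alongside the usual hit statistics:
#' qseqid qlen qstart qend sacc sstart send evalue bitscore length pident
#' qcovhsp qseq sseq.
#'
#' @return character vector of the 14 internal column names.
#' @export
blast_tab_columns <- function() {
  c("query_id", "query_len", "q_start", "q_end", "subject_acc",
    "s_start", "s_end", "evalue", "bitscore", "aln_len",
    "pct_identity", "q_coverage", "q_seq", "s_seq")
}

#' Read a homology hit table (14-column BLAST tabular dialect)
#'
#' Parses a headerless tab-separated hit table with exactly the 14 columns of
#' [blast_tab_columns()] and attaches a species label to every row. Subject
#' coordinates are kept as reported: `s_start > s_end` marks a minus-strand
#' hit; aligned sequences are stored query-oriented as given, so no
#' reverse-complementing is ever needed downstream.
#'
#' @param path path to the tab-separated hit file, no header.
#' @param species species label attached to every row of this file.
#' @return a `data.frame` with the columns of [blast_tab_columns()] plus
#'   `species`, one row per hit, input order preserved.
#' @export
read_blast_tab <- function(path, species) {
  stopifnot(is.character(species), length(species) == 1L)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(
      c(list(character()), list(integer()), list(integer()), list(integer()),
        list(character()), list(integer()), list(integer()), list(numeric()),
        list(numeric()), list(integer()), list(numeric()), list(numeric()),
        list(character()), list(character())),
      blast_tab_columns()))
    out$species <- character()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 14L)) {
    bad <- which(nf != 14L)[1L]
    stop(sprintf(
      "malformed hit row at line %d of %s: %d columns, expected 14 (dialect: qseqid qlen qstart qend sacc sstart send evalue bitscore length pident qcovhsp qseq sseq)",
      bad, path, nf[bad]))
  }
  m <- do.call(rbind, parts)
  num_cols <- c(2, 3, 4, 6, 7, 8, 9, 10, 11, 12)
  vals <- suppressWarnings(apply(m[, num_cols, drop = FALSE], 2, as.numeric))
  vals <- matrix(vals, nrow = nrow(m))
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1L]
    stop(sprintf("non-numeric value in a numeric field at line %d of %s", bad, path))
  }
  out <- data.frame(
    query_id     = m[, 1], query_len = as.integer(vals[, 1]),
    q_start      = as.integer(vals[, 2]), q_end = as.integer(vals[, 3]),
    subject_acc  = m[, 5],
    s_start      = as.integer(vals[, 4]), s_end = as.integer(vals[, 5]),
    evalue       = vals[, 6], bitscore = vals[, 7],
    aln_len      = as.integer(vals[, 8]),
    pct_identity = vals[, 9], q_coverage = vals[, 10],
    q_seq        = m[, 13], s_seq = m[, 14],
    stringsAsFactors = FALSE)
  if (any(out$evalue < 0)) stop("negative e-value in ", path)
  if (any(out$pct_identity < 0 | out$pct_identity > 100))
    stop("percent identity outside [0, 100] in ", path)
  bad_len <- nchar(out$q_seq) != out$aln_len | nchar(out$s_seq) != out$aln_len
  if (any(bad_len))
    warning(sum(bad_len), " row(s) in ", path,
            " have aligned sequence length differing from the reported alignment length")
  out$species <- normalize_species(species)
  out
}

#' Write a homology hit table
#'
#' Inverse of [read_blast_tab()]; drops the attached `species` column.
#'
#' @param hits data.frame as returned by [read_blast_tab()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  cols <- blast_tab_columns()
  m <- as.matrix(format(hits[, cols], trim = TRUE, scientific = FALSE))
  # evalue keeps its scientific form; re-emit numerics compactly
  for (j in c("evalue", "bitscore", "pct_identity", "q_coverage"))
    m[, j] <- vapply(hits[[j]], format, "", trim = TRUE)
  writeLines(apply(m, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()]: record ids are the
#' first whitespace-delimited token of the header, sequences are uppercased,
#' record order is preserved. Duplicate ids are an error; characters outside
#' the IUPAC set raise a warning but are retained.
#'
#' @param path path to a FASTA file (folded or unfolded).
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  odd <- grepl("[^ACGTUNRYSWKMBDHV-]", seqs)
  if (any(odd))
    warning("non-IUPAC characters retained in record(s): ",
            paste(ids[odd], collapse = ", "))
  seqs
}

#' Write a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for folding (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a phylogeny from a Newick file
#'
#' Reads a single rooted tree with branch lengths via [ape::read.tree()],
#' normalizes tip labels with [normalize_species()], and validates that every
#' edge carries a branch length (the phylogenetic covariance is undefined
#' otherwise). Zero-length branches are accepted with a warning.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] object with normalized tip labels.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  # spaces inside unquoted labels are underscores in every other tool's
  # output; convert before parsing so normalization sees them
  txt <- gsub("(?<=[A-Za-z0-9_.'-]) +(?=[A-Za-z0-9_.'-])", "_", txt,
              perl = TRUE)
  tr <- ape::read.tree(text = txt)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single Newick tree in ", path)
    tr <- tr[[1L]]
  }
  if (is.null(tr)) stop("could not parse a Newick tree from ", path)
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length))
    stop("tree in ", path, " is missing branch lengths on one or more edges")
  if (any(tr$edge.length < 0))
    stop("tree in ", path, " has negative branch lengths")
  if (any(tr$edge.length == 0))
    warning("tree in ", path, " contains zero-length branches")
  tr$tip.label <- normalize_species(tr$tip.label)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels after species-name normalization: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Write a phylogeny to a Newick file
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a species trait table
#'
#' Reads a CSV of species maximum lifespans (AnAge-style: columns `species`
#' and `max_longevity_yrs`), normalizes species names, drops rows with missing
#' or nonpositive lifespans with a warning, and applies per-species overrides
#' after loading. The default override caps the human maximum lifespan at 90
#' years: the verified human record of 122 years reflects an enormous sample
#' size relative to every other species, so the conventional cap keeps the
#' human datum comparable. Each row carries a provenance flag.
#'
#' @param path path to the CSV file (header required).
#' @param overrides named numeric vector, species name to lifespan in years,
#'   applied after load; overridden rows are flagged `"override"`. An override
#'   for a species absent from the file adds a row flagged `"inferred"`.
#' @return data.frame with columns `species`, `max_lifespan_yrs`, `provenance`.
#' @export
read_trait_table <- function(path, overrides = c(Homo_sapiens = 90)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "max_longevity_yrs")
  if (!all(need %in% names(tab)))
    stop("trait CSV must contain columns: ", paste(need, collapse = ", "))
  out <- data.frame(
    species = normalize_species(tab$species),
    max_lifespan_yrs = as.numeric(tab$max_longevity_yrs),
    provenance = "observed",
    stringsAsFactors = FALSE)
  bad <- is.na(out$max_lifespan_yrs) | out$max_lifespan_yrs <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " row(s) with missing or nonpositive lifespan: ",
            paste(out$species[bad], collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  if (anyDuplicated(out$species))
    stop("duplicate species after normalization: ",
         paste(unique(out$species[duplicated(out$species)]), collapse = ", "))
  if (length(overrides)) {
    stopifnot(!is.null(names(overrides)), all(overrides > 0))
    ov_names <- normalize_species(names(overrides))
    for (i in seq_along(overrides)) {
      j <- match(ov_names[i], out$species)
      if (is.na(j)) {
        out <- rbind(out, data.frame(species = ov_names[i],
                                     max_lifespan_yrs = unname(overrides[i]),
                                     provenance = "inferred"))
      } else {
        out$max_lifespan_yrs[j] <- unname(overrides[i])
        out$provenance[j] <- "override"
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Read / write the per-locus results table
#'
#' The results TSV has one row per promoter with columns locus, gene,
#' n_species, cpg_density_mean, slope, se, t, p, q, lambda, direction.
#'
#' @param path path to the TSV.
#' @return data.frame of results.
#' @export
read_results_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_results_tsv
#' @param results results data.frame (see [run_lifespan_scan()]).
#' @export
write_results_tsv <- function(results, path) {
  df <- as.data.frame(results)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(v) ifelse(is.na(v), NA, format(v, digits = 15, trim = TRUE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
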