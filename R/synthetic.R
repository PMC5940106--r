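# Run expr under a temporary seed, restoring the caller's RNG stream after.
# seed = NULL draws from the current stream (no save/restore needed).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Fold a few small integers into one deterministic 32-bit-safe seed.
derive_seed <- function(...) {
  v <- as.numeric(c(...))
  as.integer(sum(v * 9973^(seq_along(v) - 1)) %% 2147483399)
}

#' Configuration of the synthetic dataset generator
#'
#' Bundles every knob of the generator with defaults chosen to emulate the
#' study regime the pipeline targets: a few dozen species on an ultrametric
#' tree, log-lifespan evolving by Brownian motion, ~5% of loci with a planted
#' positive density-lifespan association and ~0.3% negative, the rest null,
#' with promoter-like CpG densities around 0.06 per nt. Effect sizes default
#' to values giving roughly 80% per-locus power at 64 tips (calibrated once
#' by simulation and frozen here).
#'
#' @param n_tips number of species (>= 3).
#' @param n_loci number of promoter loci.
#' @param prop_pos,prop_neg fractions of loci with planted positive /
#'   negative associations (sum <= 1).
#' @param beta_pos,beta_neg planted slope magnitudes, density units per
#'   log-year.
#' @param sigma2_bm Brownian-motion rate of log-lifespan (variance per unit
#'   tree depth; trees are unit-depth, so this is the tip variance).
#' @param lambda_true Pagel's lambda of the simulated lifespans in `[0, 1]`.
#' @param root_log_lifespan root state of the lifespan walk (default
#'   `log(28)`, a typical mammalian mean maximum lifespan in years).
#' @param locus_phylo_noise_sd,locus_iid_noise_sd density-unit standard
#'   deviations of the phylogenetic and iid noise added to each locus.
#' @param density_center target mean CpG density of a locus (per nt).
#' @param seq_len emitted promoter length, nt (>= 50; default 600, the
#'   -499..+100 promoter window).
#' @param gc_target target GC percent of emitted sequences.
#' @param identity_range range percent identities assigned to true hit rows.
#' @param decoy_frac fraction of loci per species receiving an extra sub-70%
#'   identity decoy hit row.
#' @param dup_frac fraction receiving an extra lower-bitscore duplicate row.
#' @param seed integer seed controlling the whole dataset.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_tips = 64, n_loci = 400,
                       prop_pos = 0.05, prop_neg = 0.003,
                       beta_pos = 0.010, beta_neg = 0.010,
                       sigma2_bm = 0.6, lambda_true = 1,
                       root_log_lifespan = log(28),
                       locus_phylo_noise_sd = 0.015,
                       locus_iid_noise_sd = 0.002,
                       density_center = 0.06,
                       seq_len = 600, gc_target = 50,
                       identity_range = c(70.5, 99.9),
                       decoy_frac = 0.1, dup_frac = 0.1,
                       seed = 1L) {
  stopifnot(n_tips >= 3, n_loci >= 1, prop_pos + prop_neg <= 1,
            prop_pos >= 0, prop_neg >= 0, beta_pos > 0, beta_neg > 0,
            sigma2_bm >= 0, lambda_true >= 0, lambda_true <= 1,
            locus_phylo_noise_sd >= 0, locus_iid_noise_sd >= 0,
            seq_len >= 50, gc_target > 0, gc_target < 100)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth topology via [ape::rphylo()], branch lengths rescaled so every
#' root-to-tip path equals 1 (a unit-depth chronogram). Tips are labeled
#' `sp_01 ...`. Deterministic per seed; the caller's RNG stream is restored.
#'
#' @param n_tips number of tips (>= 3).
#' @param seed integer seed (NULL draws from the current stream).
#' @return an ultrametric [ape::phylo].
#' @export
gen_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 3) stop("need at least 3 tips")
  with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
    tr$tip.label <- sprintf("sp_%0*d", nchar(as.character(n_tips)),
                            seq_len(n_tips))
    tr
  })
}

#' Simulate a trait by Brownian motion with a lambda signal
#'
#' Draws tip values from `N(root_value, sigma2 * V(lambda))` where `V` is the
#' tree's Brownian covariance with Pagel's lambda applied. For `lambda = 1`
#' the walk is simulated branchwise (independent Gaussian increments down the
#' tree); otherwise via the Cholesky factor of the transformed covariance.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param root_value trait value at the root.
#' @param sigma2 Brownian rate (variance per unit branch length), >= 0.
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @param seed integer seed (NULL draws from the current stream).
#' @return named numeric vector of tip values.
#' @export
sim_bm <- function(tree, root_value, sigma2, lambda = 1, seed = NULL) {
  stopifnot(sigma2 >= 0)
  with_seed(seed, {
    n <- length(tree$tip.label)
    if (sigma2 == 0)
      return(stats::setNames(rep(root_value, n), tree$tip.label))
    if (lambda == 1) {
      tr <- ape::reorder.phylo(tree, "postorder")
      nnode <- n + tr$Nnode
      val <- numeric(nnode)
      root <- n + 1L
      val[root] <- root_value
      # preorder: parents before children
      ord <- rev(seq_len(nrow(tr$edge)))
      inc <- stats::rnorm(nrow(tr$edge), 0, sqrt(sigma2 * tr$edge.length))
      for (e in ord)
        val[tr$edge[e, 2L]] <- val[tr$edge[e, 1L]] + inc[e]
      stats::setNames(val[seq_len(n)], tr$tip.label)
    } else {
      C <- ape::vcv(tree)
      V <- sigma2 * lambda_transform(C, lambda)
      L <- chol(V + diag(1e-12, n))
      z <- stats::rnorm(n)
      stats::setNames(root_value + drop(t(L) %*% z), rownames(C))
    }
  })
}

#' Generate per-species CpG densities for one locus
#'
#' Inverts the analysis model into a generator: for a locus of class
#' `positive` / `negative` / `null` the density is
#' `center + s * beta * (trait - mean(trait)) + phylo_noise + iid_noise`
#' with `s = +1 / -1 / 0`, centering the expected density on `center`.
#' Phylogenetic noise is a zero-mean Brownian draw on the tree. Densities
#' are clamped to the biologically plausible band `[0.005, 0.45]`; clamping
#' more than 20% of species triggers a warning (the planted effect may be
#' attenuated).
#'
#' @param trait named vector of log-lifespans (tips of `tree`).
#' @param class `"positive"`, `"negative"` or `"null"`.
#' @param beta planted slope magnitude (> 0), density per log-year.
#' @param phylo_sd,iid_sd noise standard deviations in density units.
#' @param tree the phylogeny (needed for the phylogenetic noise).
#' @param center target mean density.
#' @param seed integer seed (NULL draws from the current stream).
#' @return named numeric vector of densities.
#' @export
gen_locus_density <- function(trait, class = c("null", "positive", "negative"),
                              beta = 0.010, phylo_sd = 0.015, iid_sd = 0.002,
                              tree = NULL, center = 0.06, seed = NULL) {
  class <- match.arg(class)
  stopifnot(beta > 0)
  s <- switch(class, positive = 1, negative = -1, null = 0)
  with_seed(seed, {
    phylo <- if (phylo_sd > 0) {
      if (is.null(tree)) stop("tree required for phylogenetic noise")
      pn <- sim_bm(tree, 0, phylo_sd^2)
      pn[names(trait)] - mean(pn[names(trait)])
    } else 0
    iid <- stats::rnorm(length(trait), 0, iid_sd)
    d <- center + s * beta * (trait - mean(trait)) + phylo + iid
    clamped <- d < 0.005 | d > 0.45
    d <- pmin(pmax(d, 0.005), 0.45)
    if (mean(clamped) > 0.2)
      warning(sprintf("density clamping affected %.0f%% of species; planted effect may be attenuated",
                      100 * mean(clamped)))
    stats::setNames(d, names(trait))
  })
}

#' Render a CpG density as a sequence with that exact CpG count
#'
#' Builds a sequence of length `seq_len` whose CpG count equals
#' `round(density * seq_len)` exactly: the required number of non-adjacent CG
#' dinucleotides is placed uniformly at random (via the classic
#' non-overlapping-dominoes bijection), remaining positions are filled from a
#' letter pool targeting `gc_target` percent G+C while never writing a G
#' immediately after a C, and a final repair scan demotes any residual
#' unplanned CpG and rebalances GC. The realized GC lands within about 2
#' points of the target.
#'
#' @param density requested CpG density in `[0, 0.5)`.
#' @param seq_len sequence length, nt.
#' @param gc_target target GC percent.
#' @param seed integer seed (NULL draws from the current stream).
#' @return a single uppercase sequence string.
#' @export
density_to_sequence <- function(density, seq_len, gc_target = 50, seed = NULL) {
  stopifnot(density >= 0, density < 0.5, seq_len >= 2)
  k <- round(density * seq_len)
  if (k > floor(seq_len / 2))
    stop("requested CpG count ", k, " cannot fit in ", seq_len, " nt")
  with_seed(seed, {
    s <- character(seq_len)
    if (k > 0) {
      q <- sort(sample.int(seq_len - k, k))
      starts <- q + seq_len(k) - 1L
      s[starts] <- "C"; s[starts + 1L] <- "G"
    }
    free <- which(s == "")
    m <- length(free)
    if (m > 0) {
      g <- round(seq_len * gc_target / 100) - 2L * k
      if (g < 0)
        warning(sprintf("gc_target %.1f%% unreachable: %d CpGs alone give %.1f%% GC",
                        gc_target, k, 200 * k / seq_len))
      g <- max(0L, min(m, g))
      n_g <- floor(g / 2); n_c <- g - n_g
      n_a <- ceiling((m - g) / 2); n_t <- (m - g) - n_a
      pool <- sample(c(rep("G", n_g), rep("C", n_c),
                       rep("A", n_a), rep("T", n_t)))
      for (i in seq_along(free)) {
        pos <- free[i]
        if (pool[i] == "G" && pos > 1L && s[pos - 1L] == "C") {
          j <- i + which(pool[(i + 1):length(pool)] != "G")[1L]
          if (!is.na(j) && i < length(pool)) {
            tmp <- pool[i]; pool[i] <- pool[j]; pool[j] <- tmp
          } else pool[i] <- "A"
        }
        s[pos] <- pool[i]
      }
    }
    seq <- paste(s, collapse = "")
    # repair scan: demote unplanned CpGs, rebalance GC where safe
    planned <- if (k > 0) starts else integer()
    repeat {
      hits <- gregexpr("CG", seq, fixed = TRUE)[[1L]]
      extra <- setdiff(hits[hits > 0], planned)
      if (!length(extra)) break
      ch <- strsplit(seq, "")[[1L]]
      ch[extra + 1L] <- "A"
      for (dummy in extra) {   # re-balance: one A/T -> G at a safe spot
        at <- which(ch %in% c("A", "T"))
        safe <- at[at == 1L | ch[pmax(at - 1L, 1L)] != "C"]
        safe <- setdiff(safe, c(extra + 1L, planned, planned + 1L))
        if (length(safe)) ch[safe[1L]] <- "G"
      }
      seq <- paste(ch, collapse = "")
    }
    realized <- cpg_count(seq)
    if (realized != k)
      stop("internal error: realized CpG count ", realized, " != requested ", k)
    seq
  })
}

#' Simulate the statistical layer of a dataset in memory
#'
#' Generates the tree, the Brownian log-lifespans and every locus's planted
#' density vector — everything except sequence rendering and file output —
#' deterministically from `config$seed`, with the same per-locus seed
#' derivation as [emit_dataset()]: the densities returned here are exactly
#' the ones a full emitted dataset realizes (`quantized` reproduces the
#' count-granularity the pipeline recovers from sequences,
#' `round(d * seq_len) / seq_len`). This is the fast path for calibration
#' studies that fit thousands of loci.
#'
#' @param config a [sim_config()].
#' @return list with `tree`, `log_lifespan` (named vector), `classes`
#'   (named by locus id), `beta_true` (signed, per locus), `density` and
#'   `density_quantized` (loci x species matrices), and `config`.
#' @export
sim_density_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  tree <- gen_tree(cfg$n_tips, seed = cfg$seed)
  logy <- sim_bm(tree, cfg$root_log_lifespan, cfg$sigma2_bm, cfg$lambda_true,
                 seed = derive_seed(cfg$seed, 1))
  n_pos <- round(cfg$n_loci * cfg$prop_pos)
  n_neg <- round(cfg$n_loci * cfg$prop_neg)
  classes <- rep(c("positive", "negative", "null"),
                 c(n_pos, n_neg, cfg$n_loci - n_pos - n_neg))
  ids <- sprintf("P%0*d", nchar(as.character(cfg$n_loci)), seq_len(cfg$n_loci))
  dens <- matrix(NA_real_, cfg$n_loci, cfg$n_tips,
                 dimnames = list(ids, names(logy)))
  beta_true <- numeric(cfg$n_loci)
  for (i in seq_len(cfg$n_loci)) {
    cls <- classes[i]
    beta <- switch(cls, positive = cfg$beta_pos, negative = cfg$beta_neg,
                   null = cfg$beta_pos)
    beta_true[i] <- switch(cls, positive = beta, negative = -beta, null = 0)
    dens[i, ] <- gen_locus_density(logy, cls, beta,
                                   cfg$locus_phylo_noise_sd,
                                   cfg$locus_iid_noise_sd,
                                   tree, cfg$density_center,
                                   seed = derive_seed(cfg$seed, 2, i))
  }
  list(tree = tree, log_lifespan = logy,
       classes = stats::setNames(classes, ids),
       beta_true = stats::setNames(beta_true, ids),
       density = dens,
       density_quantized = round(dens * cfg$seq_len) / cfg$seq_len,
       config = cfg)
}

#' Emit a complete synthetic dataset to disk
#'
#' Writes everything the pipeline consumes, all derived deterministically
#' from `config$seed`:
#' \itemize{
#'   \item `tree.nwk` — ultrametric Yule tree;
#'   \item `traits.csv` — species and maximum lifespans in years
#'     (`exp` of the simulated Brownian log-lifespans);
#'   \item `loci/<locus>.fa` — per-locus multi-species FASTA whose sequences
#'     realize the planted densities exactly;
#'   \item `truth.tsv` — the truth table: locus class, planted slope, and
#'     per-species planted density and realized CpG count;
#'   \item optionally `hits/<species>.tsv` — 14-column homology hit tables,
#'     including sub-70%-identity decoy rows and lower-scoring duplicate rows
#'     to exercise the hit filter.
#' }
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param blast also emit per-species hit tables (default TRUE).
#' @return invisibly, a list with the tree, the trait table, the truth table
#'   (data.frame) and the locus class assignment.
#' @export
emit_dataset <- function(config, outdir, blast = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stop("output directory not writable: ", outdir)
  dir.create(file.path(outdir, "loci"), showWarnings = FALSE)
  cfg <- config
  sim <- sim_density_dataset(cfg)
  tree <- sim$tree
  logy <- sim$log_lifespan
  classes <- unname(sim$classes)
  ids <- names(sim$classes)
  write_newick(tree, file.path(outdir, "tree.nwk"))
  traits <- data.frame(species = names(logy),
                       max_longevity_yrs = exp(logy))
  utils::write.csv(traits, file.path(outdir, "traits.csv"), row.names = FALSE,
                   quote = FALSE)
  genes <- sprintf("GENE%0*d", nchar(as.character(cfg$n_loci)),
                   seq_len(cfg$n_loci))
  truth <- vector("list", cfg$n_loci)
  seqs_by_locus <- vector("list", cfg$n_loci)
  for (i in seq_len(cfg$n_loci)) {
    cls <- classes[i]
    d <- sim$density[i, ]
    seqs <- vapply(seq_along(d), function(j)
      density_to_sequence(d[j], cfg$seq_len, cfg$gc_target,
                          seed = derive_seed(cfg$seed, 3 + i, j)),
      "")
    names(seqs) <- names(d)
    seqs_by_locus[[i]] <- seqs
    write_fasta(seqs, file.path(outdir, "loci", paste0(ids[i], ".fa")))
    truth[[i]] <- data.frame(
      locus = ids[i], gene = genes[i], class = cls,
      beta_true = sim$beta_true[[i]],
      species = names(d),
      density_true = unname(d),
      cpg_count_realized = cpg_count(unname(seqs)),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  utils::write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (blast) {
    dir.create(file.path(outdir, "hits"), showWarnings = FALSE)
    for (j in seq_len(cfg$n_tips)) {
      sp <- tree$tip.label[j]
      rows <- with_seed(derive_seed(cfg$seed, 5, j), {
        lapply(seq_len(cfg$n_loci), function(i) {
          seq <- seqs_by_locus[[i]][[sp]]
          pid <- round(stats::runif(1, cfg$identity_range[1],
                                    cfg$identity_range[2]), 2)
          sstart <- sample.int(1e6, 1)
          r <- data.frame(query_id = ids[i], query_len = cfg$seq_len,
                          q_start = 1L, q_end = cfg$seq_len,
                          subject_acc = "chr1", s_start = sstart,
                          s_end = sstart + cfg$seq_len - 1L,
                          evalue = 1e-180, bitscore = round(10 * pid, 1),
                          aln_len = cfg$seq_len, pct_identity = pid,
                          q_coverage = 100, q_seq = seq, s_seq = seq,
                          stringsAsFactors = FALSE)
          if (stats::runif(1) < cfg$dup_frac) {
            dup <- r; dup$subject_acc <- "chr2"
            dup$bitscore <- r$bitscore - 50; dup$evalue <- 1e-150
            r <- rbind(r, dup)
          }
          if (stats::runif(1) < cfg$decoy_frac) {
            dec <- r[1L, ]
            dec$subject_acc <- "decoy"
            dec$pct_identity <- round(stats::runif(1, 50, 69.9), 2)
            dec$bitscore <- round(10 * dec$pct_identity, 1)
            dec$evalue <- 1e-20
            dec$s_seq <- paste(sample(strsplit(dec$s_seq, "")[[1L]]),
                               collapse = "")
            r <- rbind(r, dec)
          }
          r
        })
      })
      tab <- do.call(rbind, rows)
      tab$species <- normalize_species(sp)
      write_blast_tab(tab, file.path(outdir, "hits", paste0(sp, ".tsv")))
    }
  }
  invisible(list(tree = tree, traits = traits, truth = truth,
                 classes = stats::setNames(classes, ids), config = cfg))
}
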