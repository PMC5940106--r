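#' Benjamini-Hochberg adjustment to q-values
#'
#' Step-up FDR adjustment: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, mapped back to input
#' order. Delegates to [stats::p.adjust()] after validating the family:
#' skipped loci must be excluded before adjustment so they never consume
#' multiplicity.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric())
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1))
    stop("p-values must all lie in (0, 1]; exclude skipped loci before adjustment")
  stats::p.adjust(pvals, method = "BH")
}

#' Classify a locus result by direction
#'
#' A locus is `positive` iff `q < alpha` and its slope is > 0, `negative` iff
#' `q < alpha` and slope < 0, otherwise `ns`. A slope of exactly zero is
#' never called significant in either direction.
#'
#' @param q q-value(s).
#' @param slope fitted slope(s).
#' @param alpha significance level in (0, 1), default 0.05.
#' @return character vector in `{"positive", "negative", "ns"}`.
#' @export
classify_direction <- function(q, slope, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  out <- rep("ns", length(q))
  out[!is.na(q) & q < alpha & slope > 0] <- "positive"
  out[!is.na(q) & q < alpha & slope < 0] <- "negative"
  out
}

#' Per-locus lifespan scan: PGLS over every promoter, BH across loci
#'
#' Runs the full per-locus analysis: join each locus table with the trait
#' table and tree (species reconciled by [normalize_species()], optional
#' alias map and exclusion list applied), fit
#' `log(lifespan) ~ cpg_density` by PGLS with Pagel's lambda profiled by ML,
#' adjust the fitted loci's p-values by Benjamini-Hochberg, and classify each
#' locus as positively / negatively correlated or not significant at
#' `q < alpha`. The BH family is exactly the set of successfully fitted loci:
#' loci skipped for too few species (or degenerate fits) are reported with a
#' reason and never consume multiplicity.
#'
#' @param loci list of `locus_table`s (see [assemble_locus()]), or a list of
#'   named character vectors of sequences (species -> sequence), or a list of
#'   data.frames with `species` and `cpg_density` columns.
#' @param traits trait data.frame from [read_trait_table()].
#' @param tree an [ape::phylo] with branch lengths.
#' @param alpha q-value significance threshold (default 0.05).
#' @param min_n minimum complete cases per locus (default 5).
#' @param lambda `"ML"` or a fixed value in `[0, 1]`.
#' @param exclude species excluded everywhere (manual outlier list).
#' @param alias named character vector mapping data species names to tree /
#'   trait names (applied after normalization).
#' @return a `lifespan_scan`: data.frame with one row per locus (columns
#'   `locus, gene, n_species, cpg_density_mean, slope, se, t, p, q, lambda,
#'   direction`) and a `report` attribute (counts per direction, mean species
#'   per locus overall and among significant loci, skip reasons, config echo).
#' @export
run_lifespan_scan <- function(loci, traits, tree, alpha = 0.05, min_n = 5,
                              lambda = "ML", exclude = character(),
                              alias = character()) {
  stopifnot(is.list(loci), length(loci) > 0L)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (min_n < 3L) stop("min_n must be at least 3")
  exclude <- normalize_species(exclude)
  tr_map <- stats::setNames(traits$max_lifespan_yrs,
                            normalize_species(traits$species))
  rename <- function(sp) {
    sp <- normalize_species(sp)
    if (length(alias)) {
      hit <- match(sp, normalize_species(names(alias)))
      sp[!is.na(hit)] <- normalize_species(unname(alias))[hit[!is.na(hit)]]
    }
    sp
  }
  ids <- names(loci)
  rows <- vector("list", length(loci))
  skip_reason <- character(length(loci))
  for (i in seq_along(loci)) {
    lt <- loci[[i]]
    if (is.character(lt)) {
      sp <- rename(names(lt))
      dens <- cpg_density(unname(lt))
      gene <- NA_character_
      id <- if (!is.null(ids) && nzchar(ids[i])) ids[i] else paste0("locus_", i)
    } else {
      sp <- rename(lt$species)
      dens <- if ("cpg_density" %in% names(lt)) lt$cpg_density
              else cpg_density(lt$sequence)
      gene <- attr(lt, "gene") %||% NA_character_
      id <- attr(lt, "promoter_id") %||%
        (if (!is.null(ids) && nzchar(ids[i])) ids[i] else paste0("locus_", i))
    }
    keep <- !sp %in% exclude & sp %in% names(tr_map) & sp %in% tree$tip.label &
      !duplicated(sp)
    sp <- sp[keep]; dens <- dens[keep]
    n <- length(sp)
    row <- data.frame(locus = id, gene = gene, n_species = n,
                      cpg_density_mean = if (n) mean(dens) else NA_real_,
                      slope = NA_real_, se = NA_real_, t = NA_real_,
                      p = NA_real_, q = NA_real_, lambda = NA_real_,
                      direction = "skipped", stringsAsFactors = FALSE)
    if (n < min_n) {
      skip_reason[i] <- "too-few-species"
    } else {
      y <- log(unname(tr_map[sp]))
      pc <- phylo_cov(tree, sp)
      res <- if (identical(lambda, "ML")) {
        profile_lambda_ml(y, dens, pc$C)
      } else {
        list(lambda = lambda,
             fit = gls_fit(y, dens, lambda_transform(pc$C, lambda)),
             boundary_flag = "fixed")
      }
      f <- res$fit
      if (f$flag == "unfit") {
        skip_reason[i] <- "unfit"
      } else if (f$flag == "degenerate") {
        skip_reason[i] <- "degenerate-fit"
      } else {
        row$slope <- f$beta; row$se <- f$se_slope; row$t <- f$t
        row$p <- f$p; row$lambda <- res$lambda
        row$direction <- "fitted"  # placeholder until BH
      }
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  fitted_idx <- which(out$direction == "fitted")
  if (length(fitted_idx) == 0L)
    stop("no locus passed the fitting requirements (min_n = ", min_n, ")")
  out$q[fitted_idx] <- bh_adjust(out$p[fitted_idx])
  out$direction[fitted_idx] <-
    classify_direction(out$q[fitted_idx], out$slope[fitted_idx], alpha)
  rownames(out) <- NULL
  sig <- out$direction %in% c("positive", "negative")
  report <- list(
    n_loci = nrow(out),
    n_fitted = length(fitted_idx),
    n_skipped = nrow(out) - length(fitted_idx),
    skip_reasons = table(skip_reason[nzchar(skip_reason)]),
    direction_counts = c(positive = sum(out$direction == "positive"),
                         negative = sum(out$direction == "negative"),
                         ns = sum(out$direction == "ns"),
                         skipped = sum(out$direction == "skipped")),
    mean_species_overall = mean(out$n_species[fitted_idx]),
    mean_species_significant = if (any(sig)) mean(out$n_species[sig]) else NA_real_,
    alpha = alpha, min_n = min_n, lambda = lambda,
    excluded_species = exclude)
  attr(out, "report") <- report
  class(out) <- c("lifespan_scan", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lifespan_scan <- function(x, ...) {
  r <- attr(x, "report")
  cat("Per-locus lifespan scan\n")
  cat(sprintf("  loci: %d (fitted %d, skipped %d)\n",
              r$n_loci, r$n_fitted, r$n_skipped))
  cat(sprintf("  significant at q < %g: %d positive, %d negative\n",
              r$alpha, r$direction_counts["positive"],
              r$direction_counts["negative"]))
  cat(sprintf("  mean species per fitted locus: %.1f", r$mean_species_overall))
  if (!is.na(r$mean_species_significant))
    cat(sprintf(" (significant loci: %.1f)", r$mean_species_significant))
  cat("\n")
  invisible(x)
}

#' Write the JSON run report of a scan
#'
#' @param scan a `lifespan_scan`.
#' @param path output path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_scan_report <- function(scan, path) {
  r <- attr(scan, "report")
  r$skip_reasons <- as.list(r$skip_reasons)
  r$direction_counts <- as.list(r$direction_counts)
  jsonlite::write_json(r, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
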