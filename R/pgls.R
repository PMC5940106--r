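#' Phylogenetic covariance matrix of a set of species
#'
#' Under Brownian motion on a rooted tree with branch lengths, the expected
#' trait covariance between two tips is the root-to-MRCA path length, and the
#' variance of a tip is its root-to-tip path length. This builds that matrix
#' for a given species set, pruning the tree first.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param species character vector of tip labels (normalized); at least 2.
#' @return list with elements `C` (covariance matrix in the given species
#'   order), `species`, and `tree` (the pruned tree).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' phylo_cov(tr, c("A", "B", "C"))$C
phylo_cov <- function(tree, species) {
  species <- normalize_species(species)
  if (length(species) < 2L) stop("need at least 2 species for a covariance matrix")
  if (anyDuplicated(species)) stop("duplicated species in request")
  missing <- setdiff(species, tree$tip.label)
  if (length(missing))
    stop("species absent from tree: ", paste(missing, collapse = ", "))
  # subset the full-tree covariance so depths stay measured from the
  # original root (pruning first would collapse the root stem)
  C <- ape::vcv(tree)[species, species, drop = FALSE]
  list(C = C, species = species, tree = ape::keep.tip(tree, species))
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda` in `[0, 1]`, leaving the
#' diagonal unchanged. `lambda = 0` gives phylogenetic independence (diagonal
#' matrix), `lambda = 1` pure Brownian motion.
#'
#' @param C phylogenetic covariance matrix.
#' @param lambda scalar in `[0, 1]`.
#' @return the transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  d <- diag(C)
  V <- lambda * C
  diag(V) <- d
  V
}

# Cholesky of V with the package's conditioning guard: if the reciprocal
# condition number suggests near-singularity, add one shot of
# 1e-10 * mean(diag) jitter; failing that, give up (caller flags unfit).
.chol_guarded <- function(V) {
  L <- tryCatch(chol(V), error = function(e) NULL)
  ill <- is.null(L) ||
    (nrow(V) > 1L && kappa(V, exact = FALSE) > 1e12)
  if (ill) {
    V <- V + diag(1e-10 * mean(diag(V)), nrow(V))
    L <- tryCatch(chol(V), error = function(e) NULL)
  }
  L
}

#' Generalized least squares fit of y on one predictor
#'
#' Exact GLS solution of `y = alpha + beta * x + e`, `e ~ N(0, sigma2 * V)`,
#' via Cholesky factorization (numerically equivalent to the closed-form
#' estimator `(X'V^-1 X)^-1 X'V^-1 y`). The error scale `sigma2` is the
#' maximum-likelihood (divide-by-n) estimate, used in the reported
#' log-likelihood; the slope standard error uses the df-corrected (n-2)
#' scale so the t-test has its classical reference distribution.
#'
#' @param y numeric response vector (n >= 3).
#' @param x numeric predictor vector.
#' @param V positive-definite error covariance structure matrix.
#' @return list with `beta`, `alpha`, `se_slope`, `t`, `p`, `df`, `sigma2`
#'   (ML scale), `loglik`, `n`, `flag` (`"ok"`, `"degenerate"` for a
#'   zero-residual fit, `"unfit"` for singular V or constant x; unfit
#'   results carry NA estimates).
#' @export
gls_fit <- function(y, x, V) {
  n <- length(y)
  stopifnot(length(x) == n, nrow(V) == n, ncol(V) == n)
  if (n < 3L) stop("need at least 3 observations for a slope test")
  unfit <- list(beta = NA_real_, alpha = NA_real_, se_slope = NA_real_,
                t = NA_real_, p = NA_real_, df = n - 2L, sigma2 = NA_real_,
                loglik = NA_real_, n = n, flag = "unfit")
  if (stats::var(x) == 0) return(unfit)
  L <- .chol_guarded(V)
  if (is.null(L)) return(unfit)
  X <- cbind(intercept = 1, slope = x)
  tiy <- backsolve(L, y, transpose = TRUE)
  tiX <- backsolve(L, X, transpose = TRUE)
  XtViX <- crossprod(tiX)
  beta_hat <- solve(XtViX, crossprod(tiX, tiy))
  resid <- y - drop(X %*% beta_hat)
  tie <- backsolve(L, resid, transpose = TRUE)
  rss <- sum(tie^2)
  logdetV <- 2 * sum(log(diag(L)))
  sigma2_ml <- rss / n
  flag <- "ok"
  if (sigma2_ml <= .Machine$double.eps * max(1, mean(y^2))) {
    flag <- "degenerate"
    loglik <- Inf
    se <- 0; tval <- sign(beta_hat[2]) * Inf; pval <- 0
  } else {
    loglik <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
    covb <- rss / (n - 2) * solve(XtViX)
    se <- sqrt(covb[2, 2])
    tval <- beta_hat[2] / se
    pval <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(beta = unname(beta_hat[2]), alpha = unname(beta_hat[1]),
       se_slope = unname(se), t = unname(tval), p = unname(pval),
       df = n - 2L, sigma2 = sigma2_ml, loglik = unname(loglik),
       n = n, flag = flag)
}

#' Profile Pagel's lambda by maximum likelihood
#'
#' Maximizes the GLS log-likelihood over `lambda` in `[0, 1]`: a 21-point
#' grid locates the best cell, then Brent refinement (via [stats::optimize()])
#' sharpens the optimum within the bracketing cells. A profile whose range is
#' below 1e-6 (e.g. a star phylogeny, where the off-diagonal is zero and
#' lambda has no effect) is reported as flat with `lambda = 1`.
#'
#' @param y,x response and predictor vectors.
#' @param C untransformed phylogenetic covariance matrix.
#' @return list with `lambda`, `fit` (the [gls_fit()] at the optimum),
#'   `boundary_flag` (`"interior"`, `"at0"`, `"at1"`, or `"flat"`), and
#'   `profile` (data.frame of the grid log-likelihoods).
#' @export
profile_lambda_ml <- function(y, x, C) {
  grid <- seq(0, 1, length.out = 21L)
  ll <- vapply(grid, function(l) {
    f <- gls_fit(y, x, lambda_transform(C, l))
    if (f$flag == "unfit") -Inf else f$loglik
  }, 0)
  if (all(!is.finite(ll))) {
    f <- gls_fit(y, x, lambda_transform(C, 1))
    return(list(lambda = NA_real_, fit = f, boundary_flag = "unfit",
                profile = data.frame(lambda = grid, loglik = ll)))
  }
  fin <- ll[is.finite(ll)]
  if (max(fin) - min(fin) < 1e-6) {
    lam <- 1
    flag <- "flat"
  } else {
    i <- which.max(ll)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    if (lo == hi) {
      lam <- grid[i]
    } else {
      opt <- stats::optimize(function(l) {
        f <- gls_fit(y, x, lambda_transform(C, l))
        if (f$flag == "unfit") -Inf else f$loglik
      }, interval = c(lo, hi), maximum = TRUE, tol = 1e-7)
      lam <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
    }
    # snap to the boundary when Brent stops a hair inside it
    if (lam < 1e-6) lam <- 0
    if (lam > 1 - 1e-6) lam <- 1
    flag <- if (lam == 0) "at0" else if (lam == 1) "at1" else "interior"
  }
  fit <- gls_fit(y, x, lambda_transform(C, lam))
  list(lambda = lam, fit = fit, boundary_flag = flag,
       profile = data.frame(lambda = grid, loglik = ll))
}

#' Phylogenetic generalized least squares regression
#'
#' Fits a two-trait phylogenetic regression with Pagel's lambda correlation
#' structure: `y = alpha + beta * x + e`, `e ~ N(0, sigma2 * V(lambda))`,
#' where `V(lambda)` is the Brownian-motion tip covariance of the tree with
#' off-diagonals scaled by lambda. With `lambda = "ML"` (the default) lambda
#' is estimated by profiled maximum likelihood on `[0, 1]`; a fixed numeric
#' lambda is also accepted (`lambda = 0` reduces exactly to OLS).
#'
#' The canonical use is regressing log maximum lifespan on promoter CpG
#' density:
#' `pgls(log(max_lifespan_yrs) ~ cpg_density, data, tree)`.
#'
#' Rows of `data` are matched to tree tips by the `species` column (or row
#' names if absent) after [normalize_species()]; species missing from the
#' tree or with incomplete data are dropped and recorded in the fit.
#'
#' @param formula a two-sided formula with exactly one predictor term.
#' @param data data.frame containing the variables and a `species` column
#'   (or species as row names).
#' @param tree an [ape::phylo] with branch lengths.
#' @param lambda `"ML"` or a fixed value in `[0, 1]`.
#' @param min_n minimum number of complete cases required to fit (default 5).
#' @return an object of class `"pgls"` with the usual accessor methods
#'   (`print`, `summary`, `coef`, `predict`, `residuals`, `fitted`,
#'   `logLik`, `nobs`, `plot`, `simulate`). Includes a Pearson correlation
#'   of the model-frame variables as a non-phylogenetic diagnostic.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):0.5,(C:0.8,D:0.8):0.7);")
#' d <- data.frame(species = c("A", "B", "C", "D"),
#'                 cpg_density = c(0.04, 0.05, 0.08, 0.10),
#'                 max_lifespan_yrs = c(12, 15, 40, 60))
#' fit <- pgls(log(max_lifespan_yrs) ~ cpg_density, d, tr, min_n = 4)
#' coef(fit)
pgls <- function(formula, data, tree, lambda = "ML", min_n = 5) {
  cl <- match.call()
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  species <- if ("species" %in% names(data)) data$species else rownames(data)
  if (is.null(species)) stop("data needs a 'species' column or species row names")
  species <- normalize_species(species)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  if (ncol(mf) != 2L)
    stop("the model must have exactly one predictor term")
  y <- mf[[1L]]; x <- mf[[2L]]
  ok <- !is.na(y) & !is.na(x) & species %in% tree$tip.label
  dropped <- species[!ok]
  y <- y[ok]; x <- x[ok]; species <- species[ok]
  n <- length(y)
  if (n < max(3L, min_n))
    return(structure(list(call = cl, formula = formula, n = n,
                          min_n = min_n, skipped = TRUE,
                          reason = "too-few-species",
                          dropped_species = dropped),
                     class = "pgls"))
  pc <- phylo_cov(tree, species)
  if (identical(lambda, "ML")) {
    prof <- profile_lambda_ml(y, x, pc$C)
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop("lambda must be \"ML\" or a number in [0, 1]")
    f <- gls_fit(y, x, lambda_transform(pc$C, lambda))
    prof <- list(lambda = lambda, fit = f, boundary_flag = "fixed",
                 profile = NULL)
  }
  f <- prof$fit
  pearson <- suppressWarnings(stats::cor.test(x, y))
  structure(list(
    call = cl, formula = formula, species = species,
    y = y, x = x, C = pc$C, tree = pc$tree,
    coefficients = c(intercept = f$alpha, slope = f$beta),
    se_slope = f$se_slope, t = f$t, p = f$p, df = f$df,
    lambda = prof$lambda, boundary_flag = prof$boundary_flag,
    sigma2 = f$sigma2, loglik = f$loglik, n = f$n, flag = f$flag,
    profile = prof$profile,
    pearson = c(r = unname(pearson$estimate), p = pearson$p.value),
    fitted.values = f$alpha + f$beta * x,
    residuals = y - (f$alpha + f$beta * x),
    dropped_species = dropped, skipped = FALSE,
    xname = colnames(mf)[2L], yname = colnames(mf)[1L]),
    class = "pgls")
}

#' @export
print.pgls <- function(x, digits = 4, ...) {
  cat("Phylogenetic generalized least squares (Pagel's lambda)\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  if (isTRUE(x$skipped)) {
    cat(sprintf("Skipped: %s (n = %d < min_n = %d)\n", x$reason, x$n, x$min_n))
    return(invisible(x))
  }
  cat(sprintf("n = %d species; lambda = %.4g (%s); logLik = %.4f\n",
              x$n, x$lambda, x$boundary_flag, x$loglik))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @method summary pgls
#' @export
summary.pgls <- function(object, ...) {
  if (isTRUE(object$skipped)) return(object)
  ct <- cbind(Estimate = object$coefficients,
              `Std. Error` = c(NA, object$se_slope),
              `t value` = c(NA, object$t),
              `Pr(>|t|)` = c(NA, object$p))
  structure(list(call = object$call, coefficients = ct,
                 lambda = object$lambda, boundary_flag = object$boundary_flag,
                 sigma2 = object$sigma2, loglik = object$loglik,
                 n = object$n, df = object$df, flag = object$flag,
                 pearson = object$pearson),
            class = "summary.pgls")
}

#' @export
print.summary.pgls <- function(x, digits = 4, ...) {
  cat("PGLS fit, Pagel's lambda profile ML\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = digits, na.print = "")
  cat(sprintf("\nlambda-hat = %.4g (%s), sigma2 (ML) = %.4g, logLik = %.4f\n",
              x$lambda, x$boundary_flag, x$sigma2, x$loglik))
  cat(sprintf("n = %d, residual df = %d\n", x$n, x$df))
  cat(sprintf("Pearson diagnostic (no phylogeny): r = %.4f, p = %.4g\n",
              x$pearson["r"], x$pearson["p"]))
  invisible(x)
}

#' @method coef pgls
#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @method logLik pgls
#' @export
logLik.pgls <- function(object, ...) {
  structure(object$loglik, df = 4, nobs = object$n, class = "logLik")
}

#' @method nobs pgls
#' @export
nobs.pgls <- function(object, ...) object$n

#' @export
fitted.pgls <- function(object, ...) {
  stats::setNames(object$fitted.values, object$species)
}

#' Residuals of a PGLS fit
#'
#' @param object a `"pgls"` fit.
#' @param type `"response"` for raw residuals or `"normalized"` for residuals
#'   whitened by the Cholesky factor of the fitted covariance (approximately
#'   iid under the model).
#' @param ... unused.
#' @return named numeric vector.
#' @method residuals pgls
#' @export
residuals.pgls <- function(object, type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "normalized") {
    V <- lambda_transform(object$C, object$lambda) * object$sigma2
    r <- drop(backsolve(chol(V), r, transpose = TRUE))
  }
  stats::setNames(r, object$species)
}

#' Predict from a PGLS fit
#'
#' @param object a `"pgls"` fit.
#' @param newdata optional data.frame with the predictor column; omitted, the
#'   fitted values are returned.
#' @param ... unused.
#' @return numeric vector of predicted responses.
#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  x <- newdata[[object$xname]]
  if (is.null(x)) stop("newdata lacks predictor column ", object$xname)
  object$coefficients["intercept"] + object$coefficients["slope"] * x
}

#' Simulate responses from a fitted PGLS model
#'
#' Draws from `N(X beta-hat, sigma2-hat * V(lambda-hat))` at the tips.
#'
#' @param object a `"pgls"` fit.
#' @param nsim number of response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame with one column per simulation, species as row names.
#' @export
simulate.pgls <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  V <- lambda_transform(object$C, object$lambda) * object$sigma2
  L <- chol(V)
  mu <- object$fitted.values
  out <- vapply(seq_len(nsim),
                function(i) mu + drop(t(L) %*% stats::rnorm(object$n)),
                numeric(object$n))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$species
  out
}

#' Plot a PGLS fit
#'
#' Scatter of the model-frame variables with the fitted regression line.
#'
#' @param x a `"pgls"` fit.
#' @param ... passed to [graphics::plot()].
#' @method plot pgls
#' @export
plot.pgls <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = x$xname, ylab = x$yname,
                 main = sprintf("PGLS: slope = %.3g, p = %.3g, lambda = %.2f",
                                x$coefficients["slope"], x$p, x$lambda), ...)
  graphics::abline(x$coefficients["intercept"], x$coefficients["slope"],
                   col = "firebrick")
  invisible(x)
}
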