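test_that("phylogenetic covariance is shared root-to-MRCA path length", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_cov(tr, c("A", "B", "C"))$C
  expect_equal(unname(C), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))

  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_equal(unname(phylo_cov(star, c("A", "B", "C"))$C), diag(3))

  expect_equal(unname(phylo_cov(tr, c("A", "B"))$C), rbind(c(2, 1), c(1, 2)))
  expect_error(phylo_cov(tr, c("A", "ZZ")), "absent")
  expect_error(phylo_cov(tr, "A"), "at least 2")
})

test_that("lambda transform scales off-diagonals only", {
  C <- rbind(c(2, 1), c(1, 2))
  expect_equal(lambda_transform(C, 0), diag(c(2, 2)))
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0.5), rbind(c(2, 0.5), c(0.5, 2)))
  expect_error(lambda_transform(C, 1.2), "lambda")
  expect_error(lambda_transform(C, -0.1), "lambda")
})

test_that("identity covariance reduces GLS to OLS", {
  set.seed(101)
  x <- rnorm(12); y <- 1.5 * x + rnorm(12)
  f <- gls_fit(y, x, diag(12))
  o <- summary(lm(y ~ x))
  expect_equal(f$beta, unname(coef(o)[2, 1]), tolerance = 1e-10)
  expect_equal(f$se_slope, unname(coef(o)[2, 2]), tolerance = 1e-10)
  expect_equal(f$p, unname(coef(o)[2, 4]), tolerance = 1e-10)
})

test_that("a perfect linear relation is flagged degenerate", {
  x <- c(0, 1, 2, 3)
  f <- gls_fit(2 * x + 1, x, diag(4))
  expect_equal(f$beta, 2)
  expect_equal(f$alpha, 1)
  expect_equal(f$flag, "degenerate")
  # constant predictor cannot be fit
  expect_equal(gls_fit(rnorm(4), rep(1, 4), diag(4))$flag, "unfit")
})

test_that("GLS matches the explicit-inverse oracle on random trees", {
  set.seed(202)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    C <- phylo_cov(gen_tree(n), paste0("sp_", 1:n))$C
    V <- lambda_transform(C, runif(1))
    y <- rnorm(n); x <- rnorm(n)
    f <- gls_fit(y, x, V)
    o <- oracle_gls(y, x, V)
    expect_equal(f$beta, o$beta, tolerance = 1e-8)
    expect_equal(f$se_slope, o$se, tolerance = 1e-8)
    expect_equal(f$loglik, o$loglik, tolerance = 1e-8)
  }
})

test_that("lambda profile is flat on a star tree and OLS-equal", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  C <- phylo_cov(star, LETTERS[1:6])$C
  set.seed(5)
  y <- rnorm(6); x <- rnorm(6)
  pr <- profile_lambda_ml(y, x, C)
  expect_equal(pr$boundary_flag, "flat")
  expect_equal(pr$lambda, 1)
  o <- summary(lm(y ~ x))
  expect_equal(pr$fit$beta, unname(coef(o)[2, 1]), tolerance = 1e-10)
})

test_that("profiled likelihood dominates both lambda endpoints", {
  set.seed(303)
  for (i in 1:10) {
    n <- 16
    C <- phylo_cov(gen_tree(n), sprintf("sp_%02d", 1:n))$C
    y <- drop(t(chol(C)) %*% rnorm(n)); x <- rnorm(n)
    pr <- profile_lambda_ml(y, x, C)
    ll0 <- gls_fit(y, x, lambda_transform(C, 0))$loglik
    ll1 <- gls_fit(y, x, lambda_transform(C, 1))$loglik
    expect_gte(pr$fit$loglik, ll0 - 1e-9)
    expect_gte(pr$fit$loglik, ll1 - 1e-9)
  }
})

test_that("lambda-hat tracks the simulated signal regime", {
  tr <- gen_tree(48, seed = 9)
  C <- phylo_cov(tr, tr$tip.label)$C
  L <- chol(C)
  set.seed(17)
  lam_bm <- mean(replicate(60, {
    y <- drop(t(L) %*% rnorm(48))   # Brownian motion, lambda = 1
    profile_lambda_ml(y, rnorm(48), C)$lambda
  }))
  lam_iid <- mean(replicate(60, {
    y <- rnorm(48)                  # no phylogenetic signal
    profile_lambda_ml(y, rnorm(48), C)$lambda
  }))
  expect_gte(lam_bm, 0.85)
  expect_lte(lam_iid, 0.15)
})

test_that("the formula interface fits, skips, and agrees with nlme+corPagel", {
  tr <- gen_tree(24, seed = 31)
  logy <- sim_bm(tr, log(28), 0.6, 1, seed = 32)
  dens <- gen_locus_density(logy, "positive", 0.02, tree = tr, seed = 33)
  d <- data.frame(species = names(logy), cpg_density = unname(dens),
                  max_lifespan_yrs = exp(unname(logy)))
  fit <- pgls(log(max_lifespan_yrs) ~ cpg_density, d, tr)
  expect_s3_class(fit, "pgls")
  expect_equal(fit$n, 24)
  expect_gt(coef(fit)[["slope"]], 0)
  expect_equal(unname(log(90)), 4.4998, tolerance = 1e-4)  # ln-years response scale

  # independent cross-check: nlme::gls with ape's Pagel correlation, ML
  gfit <- nlme::gls(log_life ~ cpg_density,
                    data = data.frame(log_life = log(d$max_lifespan_yrs),
                                      cpg_density = d$cpg_density,
                                      species = d$species),
                    correlation = ape::corPagel(0.8, tr, form = ~ species),
                    method = "ML")
  expect_equal(unname(coef(fit)[["slope"]]), unname(coef(gfit)[2]),
               tolerance = 1e-3)
  expect_equal(fit$lambda,
               unname(coef(gfit$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-2)

  # skipping below min_n
  small <- d[1:3, ]
  sk <- pgls(log(max_lifespan_yrs) ~ cpg_density, small, tr, min_n = 5)
  expect_true(sk$skipped)
  expect_equal(sk$reason, "too-few-species")
})

test_that("pgls methods behave like a standard model object", {
  tr <- gen_tree(16, seed = 41)
  logy <- sim_bm(tr, log(28), 0.6, 1, seed = 42)
  dens <- gen_locus_density(logy, "null", tree = tr, seed = 43)
  d <- data.frame(species = names(logy), cpg_density = unname(dens),
                  max_lifespan_yrs = exp(unname(logy)))
  fit <- pgls(log(max_lifespan_yrs) ~ cpg_density, d, tr)
  expect_equal(nobs(fit), 16)
  expect_length(residuals(fit), 16)
  expect_length(residuals(fit, type = "normalized"), 16)
  expect_equal(unname(fitted(fit) + residuals(fit)), log(d$max_lifespan_yrs))
  expect_equal(unname(predict(fit, data.frame(cpg_density = 0))),
               unname(coef(fit)[["intercept"]]))
  s <- summary(fit)
  expect_s3_class(s, "summary.pgls")
  expect_output(print(s), "lambda-hat")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(16L, 3L))
  expect_equal(simulate(fit, nsim = 2, seed = 9), simulate(fit, nsim = 2, seed = 9))
})
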