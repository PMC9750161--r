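test_that("exploratory df formula matches the standard counts", {
  expect_identical(efa_df(20, 1), 170L)
  expect_identical(efa_df(20, 2), 151L)
  expect_identical(efa_df(3, 1), 0L)
  expect_identical(efa_df(6, 1), 9L)
  expect_error(efa_df(6, 4), "not identified")
})

test_that("ML factor fit recovers exact structures with zero discrepancy", {
  lam <- rep(0.6, 6)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  fit <- ml_factor_fit(R, 1, 500)
  expect_lt(fit$F_min, 1e-9)
  expect_equal(drop(fit$loadings), lam, tolerance = 1e-4)
  # identity input: perfect fit, reproduced matrix is the identity (the
  # loading direction itself is not identified there)
  fit0 <- ml_factor_fit(diag(6), 1, 500)
  expect_lt(fit0$F_min, 1e-9)
  Sig0 <- tcrossprod(fit0$loadings) + diag(fit0$uniquenesses)
  expect_equal(Sig0, diag(6), tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("ML discrepancy agrees with factanal as an independent oracle", {
  set.seed(31)
  y <- rmvn_onefactor(400, 6, 0.7)
  R <- cor(y)
  mine <- ml_factor_fit(R, 1, 400)
  oracle <- factanal(covmat = R, factors = 1, n.obs = 400, rotation = "none")
  expect_equal(mine$F_min, unname(oracle$criteria["objective"]),
               tolerance = 1e-6)
  expect_equal(abs(drop(mine$loadings)), abs(drop(oracle$loadings)),
               tolerance = 1e-4, ignore_attr = TRUE)
  # two-factor case as well
  d2 <- gen_twofactor_ordinal(500, 6, 4, 0.8, seed = 9)
  R2 <- cor(d2)
  mine2 <- ml_factor_fit(R2, 2, 500)
  oracle2 <- factanal(covmat = R2, factors = 2, n.obs = 500, rotation = "none")
  expect_equal(mine2$F_min, unname(oracle2$criteria["objective"]),
               tolerance = 1e-5)
})

test_that("fit is invariant to variable reordering and nested in k", {
  set.seed(12)
  y <- rmvn_onefactor(300, 6, 0.6)
  R <- cor(y)
  perm <- c(4, 1, 6, 2, 5, 3)
  f1 <- ml_factor_fit(R, 1, 300)
  f2 <- ml_factor_fit(R[perm, perm], 1, 300)
  expect_equal(f1$F_min, f2$F_min, tolerance = 1e-8)
  expect_lte(ml_factor_fit(R, 2, 300)$F_min, f1$F_min + 1e-10)
})

test_that("population discrepancy separates equal-threshold from mixed skew", {
  # equal thresholds: the linear model is exactly true, loadings attenuate
  Sig <- population_sigma_fac(0.9, rep(2, 6), 1)
  pd <- population_discrepancy(Sig, 1)
  expect_equal(pd$F0, 0)
  att <- dichotomized_population_correlation(
    thresholds_from_gamma(2, 1)$thresholds,
    thresholds_from_gamma(2, 1)$thresholds, 0.81)
  expect_equal(drop(pd$fit$loadings), rep(0.9 * sqrt(att$a), 6),
               tolerance = 1e-6)
  # mixed skew: the linear one-factor structure cannot hold
  SigSM <- population_sigma_fac(0.9, skew_pattern_gammas("SM", 6), 1)
  pdSM <- population_discrepancy(SigSM, 1, N = 500)
  expect_gt(pdSM$F0, 0.01)
  expect_gt(pdSM$rmsea, 0)
  expect_equal(pdSM$delta, 500 * pdSM$F0)
  # saturated k has no misfit
  expect_equal(population_discrepancy(SigSM, 6)$F0, 0)
})

test_that("DWLS fits reproduce exact inputs and recover loadings", {
  d <- generate_condition_sample(500, 6, 2, 0.6, skew_pattern = "None",
                                 seed = 14)
  pc <- polychoric_matrix(d$data)
  f1 <- dwls_fit(pc, 1)
  expect_true(f1$converged)
  expect_lt(sqrt(mean((drop(f1$loadings) - 0.6)^2)), 0.1)
  expect_lte(dwls_fit(pc, 2)$F_min, f1$F_min + 1e-10)
  # exactly reproducible input: objective ~ 0
  lam <- rep(0.5, 6)
  pc0 <- pc
  pc0$rho <- tcrossprod(lam) + diag(1 - lam^2)
  f0 <- dwls_fit(pc0, 1)
  expect_lt(f0$F_min, 1e-10)
})

test_that("robust corrections reduce to no-ops when Gamma matches the weights", {
  d <- generate_condition_sample(500, 6, 1, 0.6, skew_pattern = "None",
                                 seed = 15)
  pc <- polychoric_matrix(d$data)
  fit <- dwls_fit(pc, 1)
  # feed Gamma = V^{-1} (the estimator's naive variance): c = 1, a = 1, b = 0
  gam0 <- diag(fit$w)
  mc <- mean_corrected_statistic(fit, gam0)
  mv <- mean_variance_corrected_statistic(fit, gam0)
  expect_equal(mc$c, 1, tolerance = 1e-8)
  expect_equal(mc$T_M, fit$chisq, tolerance = 1e-6)
  expect_equal(mv$a, 1, tolerance = 1e-8)
  expect_equal(mv$b, 0, tolerance = 1e-6)
})

test_that("ML mean correction is near 1 for continuous normal data", {
  set.seed(16)
  cs <- replicate(60, {
    y <- rmvn_onefactor(500, 6, 0.6)
    fit <- ml_factor_fit(cor(y), 1, 500)
    mean_corrected_statistic(fit, acov_pearson(y))$c
  })
  expect_equal(mean(cs), 1, tolerance = 0.05)
})

test_that("scaled chi-square difference has the documented limits", {
  expect_equal(scaled_chisq_difference(30, 1, 20, 18, 1, 15)$dT_M, 12)
  expect_equal(scaled_chisq_difference(25, 1.3, 20, 25, 1.1, 15)$dT_M, 0)
  sd_ <- scaled_chisq_difference(40, 2, 20, 10, 0.5, 10)
  expect_equal(sd_$c_d, (2 * 20 - 0.5 * 10) / 10)
  expect_error(scaled_chisq_difference(30, 1, 10, 18, 1, 15), "restrictive")
  # degenerate scaling falls back to the unscaled difference with a flag
  fb <- scaled_chisq_difference(30, -1, 20, 18, 1, 15)
  expect_true(fb$fallback)
  expect_equal(fb$dT_M, 12)
})
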