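test_that("bivariate normal CDF matches closed forms", {
  # median-dichotomization closed form: P(X<=0, Y<=0) = 1/4 + asin(rho)/(2 pi)
  for (r in c(-0.9, -0.3, 0, 0.5041, 0.95))
    expect_equal(pbvnorm(0, 0, r), 0.25 + asin(r) / (2 * pi),
                 tolerance = 1e-12)
  # marginal reduction at infinite limits
  expect_equal(pbvnorm(1.3, Inf, 0.6), pnorm(1.3), tolerance = 1e-14)
  expect_equal(pbvnorm(-Inf, 0.2, 0.6), 0)
  # independence factorizes
  expect_equal(pbvnorm(0.7, -1.1, 0), pnorm(0.7) * pnorm(-1.1),
               tolerance = 1e-13)
  # numeric-integration oracle at a non-trivial point
  f <- function(x, y, rho)
    exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2))
  ref <- integrate(Vectorize(function(x)
    integrate(function(y) f(x, y, 0.65), -Inf, 0.8,
              rel.tol = 1e-12)$value), -Inf, -0.4, rel.tol = 1e-12)$value
  expect_equal(pbvnorm(-0.4, 0.8, 0.65), ref, tolerance = 1e-9)
  # perfect correlation limits
  expect_equal(pbvnorm(0.5, 1.5, 1), pnorm(0.5))
  expect_equal(pbvnorm(0.5, -0.2, -1), pnorm(0.5) + pnorm(-0.2) - 1)
})

test_that("threshold estimation inverts cumulative proportions and collapses empties", {
  x <- rep(c(0L, 1L), each = 50)
  expect_equal(estimate_thresholds(x, 2)$thresholds, 0, tolerance = 1e-12)
  x2 <- rep(0:2, each = 30)
  expect_equal(estimate_thresholds(x2, 3)$thresholds,
               qnorm(c(1 / 3, 2 / 3)), tolerance = 1e-12)
  # proportions ~ (0.8536, 0.1464) reproduce the gamma = 2 threshold
  x3 <- c(rep(0L, 8536), rep(1L, 1464))
  expect_equal(estimate_thresholds(x3, 2)$thresholds, qnorm(0.8536),
               tolerance = 1e-6)
  # empty boundary category collapsed and recorded
  x4 <- rep(c(0L, 1L), each = 10)
  th <- estimate_thresholds(x4, 3)
  expect_equal(th$collapsed, 1L)
  expect_length(th$thresholds, 1)
  expect_error(estimate_thresholds(rep(1L, 10), 3), "constant")
})

test_that("polychoric pair agrees with a brute-force likelihood grid", {
  d <- generate_condition_sample(400, 2, 1, 0.71, skew_pattern = "MM",
                                 seed = 21)
  pp <- polychoric_pair(d$data[, 1], d$data[, 2])
  # independent oracle: direct grid search of the same likelihood
  tab <- pp$table
  ll <- function(rho) {
    P <- skewfa:::poly_cell_probs(pp$thresholds_x, pp$thresholds_y, rho)
    sum(tab * log(pmax(P, 1e-300)))
  }
  grid <- seq(-0.999, 0.999, by = 1e-4)
  best <- grid[which.max(vapply(grid, ll, 0))]
  expect_equal(pp$rho, best, tolerance = 1e-3)
})

test_that("polychoric estimates are consistent for the latent correlation", {
  errs <- vapply(c(500, 5000, 50000), function(n) {
    d <- generate_condition_sample(n, 2, 2, 0.71, skew_pattern = "None",
                                   seed = n)
    abs(polychoric_pair(d$data[, 1], d$data[, 2])$rho - 0.71^2)
  }, 0)
  expect_lt(errs[2], 0.05)
  expect_lt(errs[3], 0.02)
  # boundary 2x2 table clamps with a flag
  x <- rep(c(0L, 1L), each = 20)
  pp <- polychoric_pair(x, x)
  expect_true(pp$clamped)
  expect_equal(abs(pp$rho), 1 - 1e-6)
})

test_that("polychoric matrix recovers one-factor structure and flags degeneracy", {
  d <- generate_condition_sample(10000, 4, 2, 0.9, skew_pattern = "None",
                                 seed = 8)
  pc <- polychoric_matrix(d$data)
  off <- pc$rho[lower.tri(pc$rho)]
  expect_equal(off, rep(0.81, 6), tolerance = 0.02)
  expect_true(isSymmetric(pc$rho))
  expect_equal(diag(pc$rho), rep(1, 4))
  # acov is symmetric PSD with positive diagonal
  expect_true(isSymmetric(pc$gamma, tol = 1e-10))
  expect_true(all(diag(pc$gamma) > 0))
  expect_gt(min(eigen(pc$gamma, symmetric = TRUE,
                      only.values = TRUE)$values), -1e-8)
  dd <- d$data; dd[, 2] <- 1L
  expect_error(polychoric_matrix(dd), "column 2")
})

test_that("influence-based variance matches the sampling variance oracle", {
  # repeated sampling oracle: n * var(rho_hat) across replicates should be
  # tracked by the threshold-corrected influence estimate
  rhos <- numeric(80); gd <- numeric(80)
  for (i in 1:80) {
    d <- generate_condition_sample(500, 2, 2, 0.71, skew_pattern = "SP",
                                   seed = 500 + i)
    pc <- polychoric_matrix(d$data)
    rhos[i] <- pc$rho_raw[2, 1]
    gd[i] <- pc$gamma[1, 1]
  }
  expect_equal(mean(gd), 500 * var(rhos), tolerance = 0.3)
})

test_that("influence-based variances stabilize as n grows", {
  # diag(Gamma) estimates the variance of sqrt(n) * rho_hat: doubling n
  # should leave it roughly unchanged
  v <- vapply(c(2000, 8000), function(n) {
    d <- generate_condition_sample(n, 2, 1, 0.71, skew_pattern = "None",
                                   seed = 77)
    pc <- polychoric_matrix(d$data)
    diag(pc$gamma)[1]
  }, 0)
  expect_equal(v[1], v[2], tolerance = 0.25)
  # independent columns: off-diagonal influence covariance near zero
  set.seed(99)
  ind <- matrix(sample(0:2, 3 * 4000, TRUE), ncol = 3)
  pc <- polychoric_matrix(ind)
  offblock <- pc$gamma[1, 2]
  expect_lt(abs(offblock), 0.15)
})

test_that("attenuation of the dichotomized correlation behaves as theory says", {
  rs <- 0.5041
  # closed form at median splits
  expect_equal(dichotomized_population_correlation(0, 0, rs)$rho_y,
               2 / pi * asin(rs), tolerance = 1e-10)
  expect_equal(dichotomized_population_correlation(1, 1, 0)$rho_y, 0,
               tolerance = 1e-12)
  # sign-flip symmetry
  a1 <- dichotomized_population_correlation(0.8, -0.3, rs)
  a2 <- dichotomized_population_correlation(-0.8, 0.3, rs)
  expect_equal(a1$rho_y, a2$rho_y, tolerance = 1e-12)
  # |rho_y| <= |rho*| over a threshold grid, maximal at (0, 0)
  grid <- expand.grid(t1 = seq(-2, 2, 0.5), t2 = seq(-2, 2, 0.5))
  ry <- mapply(function(t1, t2)
    dichotomized_population_correlation(t1, t2, rs)$rho_y,
    grid$t1, grid$t2)
  expect_true(all(abs(ry) <= rs + 1e-12))
  expect_equal(max(ry), dichotomized_population_correlation(0, 0, rs)$rho_y,
               tolerance = 1e-12)
  # opposite skew attenuates more than same skew
  expect_lt(dichotomized_population_correlation(-2, 2, rs)$rho_y,
            dichotomized_population_correlation(-2, -2, rs)$rho_y)
})

test_that("polytomous population correlation reduces to the binary case", {
  rs <- 0.36
  bin <- dichotomized_population_correlation(0.6, -0.4, rs)$rho_y
  expect_equal(ordinal_population_correlation(0.6, -0.4, rs), bin,
               tolerance = 1e-10)
  # against a simulation oracle for r = 2
  tau1 <- thresholds_from_gamma(1, 2)$thresholds
  tau2 <- thresholds_from_gamma(-1, 2)$thresholds
  set.seed(4)
  n <- 2e5
  xi <- rnorm(n)
  y1 <- 0.6 * xi + sqrt(1 - 0.36) * rnorm(n)
  y2 <- 0.6 * xi + sqrt(1 - 0.36) * rnorm(n)
  emp <- cor(findInterval(y1, tau1), findInterval(y2, tau2))
  expect_equal(ordinal_population_correlation(tau1, tau2, rs), emp,
               tolerance = 0.01)
})
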