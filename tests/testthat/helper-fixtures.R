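# Shared fixtures built in code.

# multivariate-normal one-factor continuous sample (unit variances)
rmvn_onefactor <- function(n, p, lambda, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xi <- rnorm(n)
  outer(xi, rep(lambda, p)) +
    matrix(rnorm(n * p), n, p) * sqrt(1 - lambda^2)
}

# ordinal sample from a generic two-factor categorical model
# (inter-factor correlation rf, loadings on alternating factors)
gen_twofactor_ordinal <- function(n, p, r, lambda, rf = 0.3, seed = 1) {
  set.seed(seed)
  A <- chol(matrix(c(1, rf, rf, 1), 2))
  xi <- matrix(rnorm(n * 2), n, 2) %*% A
  fac <- rep(1:2, length.out = p)
  lat <- xi[, fac] * lambda + matrix(rnorm(n * p), n, p) * sqrt(1 - lambda^2)
  tau <- thresholds_from_gamma(0, r)$thresholds
  discretize(lat, rep(list(tau), p))
}

# sample from a known one-factor GRM (logit metric)
gen_grm_sample <- function(n, slopes, bounds, seed = 1) {
  set.seed(seed)
  p <- length(slopes)
  K <- ncol(as.matrix(bounds)) + 1L
  th <- rnorm(n)
  dat <- matrix(0L, n, p)
  bounds <- as.matrix(bounds)
  for (j in seq_len(p)) {
    P <- grm_category_probs(list(slopes = matrix(slopes[j], 1),
                                 bounds = bounds[j, , drop = FALSE]),
                            1, matrix(th))
    cp <- t(apply(P, 1, cumsum))
    u <- runif(n)
    dat[, j] <- as.integer(rowSums(u > cp[, -K, drop = FALSE]))
  }
  dat
}

# printed reference thresholds (standard-normal deviates, 2 d.p.):
# rows gamma in (-2, -1, 0, 1, 2); the gamma = -1, r = 4 second entry is the
# known sign misprint and is stored here with the correct sign.
reference_thresholds <- list(
  r1 = list(`-2` = -1.05, `-1` = -0.59, `0` = 0.00, `1` = 0.59, `2` = 1.05),
  r2 = list(`-2` = c(-2.39, -0.93), `-1` = c(-1.70, -0.31),
            `0` = c(-0.67, 0.67), `1` = c(0.31, 1.70), `2` = c(0.93, 2.39)),
  r4 = list(`-2` = c(-4.32, -3.26, -2.16, -0.86),
            `-1` = c(-3.31, -2.28, -1.25, -0.08),
            `0` = c(-1.53, -0.49, 0.49, 1.53),
            `1` = c(0.08, 1.25, 2.28, 3.31),
            `2` = c(0.86, 2.16, 3.26, 4.32))
)
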