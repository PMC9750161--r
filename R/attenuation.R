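#' Population Pearson correlation of two dichotomized indicators
#'
#' For latent responses with correlation `rho_star` dichotomized at
#' thresholds `tau1`, `tau2`, returns the manifest (phi) correlation
#' `rho_y = (P11 - p1 p2) / sqrt(p1 q1 p2 q2)` with
#' `P11 = P(Y1* > tau1, Y2* > tau2)`, and the attenuation factor
#' `a = rho_y / rho_star`. Attenuation is most severe when the two items are
#' skewed in opposite directions (thresholds of opposite sign).
#'
#' @param tau1,tau2 dichotomization thresholds (standard-normal scale).
#' @param rho_star latent correlation, in (-1, 1); for a one-factor model
#'   `rho_star = lambda1 * lambda2`.
#' @return list with `tau1`, `tau2`, `rho_star`, `rho_y`, `a`.
#' @export
#' @examples
#' # median splits: rho_y = 2/pi * asin(rho_star)
#' dichotomized_population_correlation(0, 0, 0.5041)$rho_y
dichotomized_population_correlation <- function(tau1, tau2, rho_star) {
  if (abs(rho_star) >= 1) stop("rho_star must lie in (-1, 1)")
  p1 <- 1 - pnorm(tau1)
  p2 <- 1 - pnorm(tau2)
  if (p1 * (1 - p1) < 1e-300 || p2 * (1 - p2) < 1e-300)
    stop("threshold so extreme that a marginal probability underflows")
  # survival rectangle via inclusion-exclusion on the CDF
  P11 <- 1 - pnorm(tau1) - pnorm(tau2) + pbvnorm(tau1, tau2, rho_star)
  rho_y <- (P11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  list(tau1 = tau1, tau2 = tau2, rho_star = rho_star,
       rho_y = rho_y, a = if (rho_star != 0) rho_y / rho_star else NA_real_)
}

#' Population Pearson correlation of two polytomized indicators
#'
#' Generalizes [dichotomized_population_correlation()] to ordinal scoring
#' `y = #( thresholds below y* )`: with `S_j(t) = 1 - pnorm(tau_jt)`,
#' `E y_j = sum_t S_j(t)` and
#' `E y_1 y_2 = sum_s sum_t P(Y1* > tau_1s, Y2* > tau_2t)`.
#'
#' @param tau1,tau2 increasing threshold vectors for the two items.
#' @param rho_star latent correlation.
#' @return manifest Pearson correlation (scalar).
#' @export
ordinal_population_correlation <- function(tau1, tau2, rho_star) {
  S <- function(tau) 1 - pnorm(tau)
  m1 <- sum(S(tau1)); m2 <- sum(S(tau2))
  upper <- function(a, b, r) 1 - pnorm(a) - pnorm(b) + pbvnorm(a, b, r)
  g <- expand.grid(a = tau1, b = tau2)
  e12 <- sum(upper(g$a, g$b, rho_star))
  second_moment <- function(tau) {
    g <- expand.grid(a = tau, b = tau)
    sum(1 - pnorm(pmax(g$a, g$b)))
  }
  v1 <- second_moment(tau1) - m1^2
  v2 <- second_moment(tau2) - m2^2
  (e12 - m1 * m2) / sqrt(v1 * v2)
}

#' Population manifest correlation matrix of a one-factor categorical model
#'
#' Builds the exact Pearson correlation matrix of the discretized indicators
#' implied by loadings `lambda`, per-item skewness targets `gamma` and `r`
#' thresholds. This is the matrix a linear factor analysis sees in the
#' population; under mixed skewness it no longer has one-factor structure.
#'
#' @param lambda loading vector (or scalar, recycled).
#' @param gamma per-item skewness targets.
#' @param r number of thresholds.
#' @return `p x p` correlation matrix.
#' @export
population_sigma_fac <- function(lambda, gamma, r) {
  p <- max(length(lambda), length(gamma))
  lambda <- rep_len(lambda, p)
  gamma <- rep_len(gamma, p)
  taus <- lapply(gamma, function(g) thresholds_from_gamma(g, r)$thresholds)
  R <- diag(p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    R[i, j] <- R[j, i] <-
      ordinal_population_correlation(taus[[i]], taus[[j]],
                                     lambda[i] * lambda[j])
  }
  R
}
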