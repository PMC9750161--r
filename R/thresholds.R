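#' Binomial success probability for a target skewness
#'
#' The generator prescribes item skewness by giving each item a
#' Binomial(r, pi) marginal. The skewness of Binomial(r, pi) is
#' `(1 - 2*pi) / sqrt(r*pi*(1-pi))`; solving for pi gives
#' `pi = 1/2 - gamma*sqrt(r) / sqrt(16 + 4*gamma^2*r)`.
#'
#' @param gamma target skewness coefficient (finite).
#' @param r number of thresholds (K = r + 1 observed categories), `r >= 1`.
#' @return success probability in (0, 1).
#' @export
#' @examples
#' binomial_pi_from_gamma(0, 1)   # 0.5
#' binomial_pi_from_gamma(2, 1)   # ~0.14645
binomial_pi_from_gamma <- function(gamma, r) {
  if (!is.numeric(r) || r < 1 || r != round(r))
    stop("r must be an integer >= 1")
  if (!is.finite(gamma)) stop("gamma must be finite")
  0.5 - gamma * sqrt(r) / sqrt(16 + 4 * gamma^2 * r)
}

#' Standard-normal thresholds matching a binomial marginal
#'
#' Computes the cumulative probabilities of the Binomial(r, pi) distribution
#' with pi chosen by [binomial_pi_from_gamma()], and maps them to the
#' standard-normal scale: `tau_t = qnorm(pr_t)` for `t = 1..r`. Discretizing
#' a standard-normal latent response at these thresholds yields an observed
#' variable with exactly the binomial marginal, hence skewness `gamma`.
#'
#' @inheritParams binomial_pi_from_gamma
#' @return object of class `"threshold_set"`: a list with `gamma`, `r`, `pi`,
#'   `cum_probs` (length r + 1, last entry 1) and `thresholds` (length r,
#'   strictly increasing).
#' @export
#' @examples
#' thresholds_from_gamma(2, 1)$thresholds    # 1.05 to 2 d.p.
#' thresholds_from_gamma(0, 4)$thresholds    # -1.53 -0.49 0.49 1.53
thresholds_from_gamma <- function(gamma, r) {
  pi_ <- binomial_pi_from_gamma(gamma, r)
  cum <- cumsum(dbinom(0:r, r, pi_))
  cum[r + 1] <- 1
  tau <- qnorm(cum[seq_len(r)])
  if (any(!is.finite(tau)))
    stop("degenerate threshold: cumulative probability underflows to 0 or 1")
  if (any(diff(tau) <= 0)) stop("thresholds are not strictly increasing")
  structure(list(gamma = gamma, r = r, pi = pi_,
                 cum_probs = cum, thresholds = tau),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("Thresholds for gamma = %g, r = %d (pi = %.5f):\n",
              x$gamma, x$r, x$pi))
  print(round(x$thresholds, 4))
  invisible(x)
}

#' Skewness target vector for a named pattern
#'
#' Items receive skewness targets in equal blocks: `None` all 0; `SP` all +2;
#' `MM` half -1 / half +1; `SM` half -2 / half +2; `N+SM` thirds -2 / 0 / +2.
#'
#' @param pattern one of `"None"`, `"SP"`, `"MM"`, `"SM"`, `"N+SM"`.
#' @param p number of items; must be divisible by the number of blocks.
#' @return numeric vector of length `p`.
#' @export
skew_pattern_gammas <- function(pattern, p) {
  blocks <- switch(pattern,
    "None"  = 0,
    "SP"    = 2,
    "MM"    = c(-1, 1),
    "SM"    = c(-2, 2),
    "N+SM"  = c(-2, 0, 2),
    stop("unknown skew pattern: ", pattern))
  if (p %% length(blocks) != 0)
    stop(sprintf("p = %d is not divisible by the %d blocks of pattern %s",
                 p, length(blocks), pattern))
  rep(blocks, each = p / length(blocks))
}
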