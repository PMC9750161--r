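#' Standard bivariate normal CDF
#'
#' Computes `P(X <= h, Y <= k)` for a standard bivariate normal vector with
#' correlation `rho`, using the Drezner-Wesolowsky algorithm as refined by
#' Genz: Gauss-Legendre quadrature on the arcsin-transformed correlation for
#' moderate `rho`, and the tail expansion for `|rho| > 0.925`. Absolute
#' accuracy is about 1e-14, which the polychoric likelihood machinery relies
#' on.
#'
#' @param h,k upper integration limits (vectors are recycled to a common
#'   length; `-Inf`/`Inf` allowed).
#' @param rho scalar correlation in `[-1, 1]`.
#' @return vector of probabilities.
#' @export
#' @examples
#' pbvnorm(0, 0, 0.5)            # 1/4 + asin(0.5)/(2*pi)
#' pbvnorm(1.64, Inf, 0.3)       # marginal pnorm(1.64)
pbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  stopifnot(length(rho) == 1L, is.finite(rho) || abs(rho) == 1)
  if (rho > 1 || rho < -1) stop("rho must lie in [-1, 1]")
  out <- numeric(n)

  # degenerate correlations have closed forms
  if (rho == 1) return(pnorm(pmin(h, k)))
  if (rho == -1) return(pmax(0, pnorm(h) + pnorm(k) - 1))

  fin <- is.finite(h) & is.finite(k)
  # one or both limits infinite: reduce to univariate margins
  out[!fin] <- ifelse(h[!fin] == -Inf | k[!fin] == -Inf, 0,
    ifelse(h[!fin] == Inf & k[!fin] == Inf, 1,
      ifelse(h[!fin] == Inf, pnorm(k[!fin]), pnorm(h[!fin]))))
  if (any(fin)) out[fin] <- bvn_genz(h[fin], k[fin], rho)
  out
}

# Gauss-Legendre nodes/weights on [-1, 1] used by the Genz algorithm.
.gl20 <- local({
  x <- c(0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
         0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
         0.5108670019508271, 0.3737060887154196, 0.2277858511416451,
         0.0765265211334973)
  w <- c(0.0176140071391521, 0.0406014298003869, 0.0626720483341091,
         0.0832767415767048, 0.1019301198172404, 0.1181945319615184,
         0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
         0.1527533871307259)
  list(x = c(-x, x), w = c(w, w))
})

# P(X <= h, Y <= k) for finite limits, |rho| < 1. Vectorized over h, k.
bvn_genz <- function(h, k, rho) {
  gl <- .gl20
  if (abs(rho) <= 0.925) {
    hk <- h * k
    hs <- (h * h + k * k) / 2
    asr <- asin(rho)
    s <- 0
    for (i in seq_along(gl$x)) {
      sn <- sin(asr * (gl$x[i] + 1) / 2)
      s <- s + gl$w[i] * exp((sn * hk - hs) / (1 - sn * sn))
    }
    return(s * asr / (4 * pi) + pnorm(h) * pnorm(k))
  }
  # |rho| > 0.925: Genz tail formulation, computed per element
  vapply(seq_along(h), function(i) bvn_tail1(h[i], k[i], rho), numeric(1))
}

bvn_tail1 <- function(h, k, r) {
  # work with the upper-orthant form L(-h,-k,r) = P(X > -h, Y > -k)
  gl <- .gl20
  twopi <- 2 * pi
  hh <- -h; kk <- -k
  hk <- hh * kk
  bvn <- 0
  if (r < 0) { kk <- -kk; hk <- -hk }
  if (abs(r) < 1) {
    as_ <- (1 - r) * (1 + r)
    a <- sqrt(as_)
    bs <- (hh - kk)^2
    c_ <- (4 - hk) / 8
    d_ <- (12 - hk) / 16
    asr <- -(bs / as_ + hk) / 2
    if (asr > -100)
      bvn <- a * exp(asr) * (1 - c_ * (bs - as_) * (1 - d_ * bs / 5) / 3 +
                               c_ * d_ * as_ * as_ / 5)
    if (-hk < 100) {
      b <- sqrt(bs)
      sp <- sqrt(twopi) * pnorm(-b / a)
      bvn <- bvn - exp(-hk / 2) * sp * b * (1 - c_ * bs * (1 - d_ * bs / 5) / 3)
    }
    a <- a / 2
    for (i in seq_along(gl$x)) {
      xs <- (a * (gl$x[i] + 1))^2
      rs <- sqrt(1 - xs)
      asr <- -(bs / xs + hk) / 2
      if (asr > -100) {
        sp <- 1 + c_ * xs * (1 + d_ * xs)
        ep <- exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs
        bvn <- bvn + a * gl$w[i] * exp(asr) * (ep - sp)
      }
    }
    bvn <- -bvn / twopi
  }
  if (r > 0) {
    bvn <- bvn + pnorm(-max(hh, kk))
  } else {
    bvn <- -bvn
    if (kk > hh) bvn <- bvn + pnorm(kk) - pnorm(hh)
  }
  bvn
}

#' Standard bivariate normal density
#'
#' @param h,k coordinates (recycled); non-finite coordinates give density 0.
#' @param rho scalar correlation with `|rho| < 1`.
#' @return vector of densities.
#' @export
dbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  out <- numeric(n)
  fin <- is.finite(h) & is.finite(k)
  om <- 1 - rho^2
  out[fin] <- exp(-(h[fin]^2 - 2 * rho * h[fin] * k[fin] + k[fin]^2) /
                    (2 * om)) / (2 * pi * sqrt(om))
  out
}
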