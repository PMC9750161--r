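#' Threshold estimates for one ordinal variable
#'
#' Step 1 of two-step polychoric estimation: thresholds are inverse-normal
#' transforms of the cumulative category proportions. Categories that are
#' empty in the sample are collapsed into their neighbour and recorded, so
#' the returned thresholds are strictly increasing.
#'
#' @param column integer vector with entries in `0..K-1`.
#' @param K intended number of categories (defaults to `max(column) + 1`).
#' @return list with `thresholds` (length = observed categories - 1),
#'   `levels` (the observed category labels after collapsing), `codes`
#'   (the column recoded to `0..(m-1)`), and `collapsed` (number of empty
#'   categories dropped).
#' @export
estimate_thresholds <- function(column, K = max(column) + 1L) {
  counts <- tabulate(column + 1L, nbins = K)
  obs <- which(counts > 0L)
  if (length(obs) < 2L)
    stop("variable is constant: cannot estimate thresholds")
  m <- length(obs)
  props <- counts[obs] / length(column)
  tau <- qnorm(cumsum(props)[-m])
  codes <- match(column + 1L, obs) - 1L
  list(thresholds = tau, levels = obs - 1L, codes = as.integer(codes),
       collapsed = K - m)
}

# cell probabilities of the contingency table implied by thresholds and rho
poly_cell_probs <- function(tau_x, tau_y, rho) {
  ax <- c(-Inf, tau_x, Inf)
  ay <- c(-Inf, tau_y, Inf)
  Phi <- matrix(pbvnorm(rep(ax, times = length(ay)),
                        rep(ay, each = length(ax)), rho),
                length(ax), length(ay))
  nr <- length(tau_x) + 1L
  nc <- length(tau_y) + 1L
  P <- Phi[-1, -1, drop = FALSE] - Phi[-nrow(Phi), -1, drop = FALSE] -
    Phi[-1, -ncol(Phi), drop = FALSE] + Phi[-nrow(Phi), -ncol(Phi), drop = FALSE]
  pmax(P, 0)
}

# derivative of each cell probability with respect to rho
poly_cell_dprobs <- function(tau_x, tau_y, rho) {
  ax <- c(-Inf, tau_x, Inf)
  ay <- c(-Inf, tau_y, Inf)
  phi <- matrix(dbvnorm(rep(ax, times = length(ay)),
                        rep(ay, each = length(ax)), rho),
                length(ax), length(ay))
  phi[-1, -1, drop = FALSE] - phi[-nrow(phi), -1, drop = FALSE] -
    phi[-1, -ncol(phi), drop = FALSE] + phi[-nrow(phi), -ncol(phi), drop = FALSE]
}

#' Two-step polychoric correlation for a pair of ordinal variables
#'
#' With thresholds fixed at their univariate estimates, the latent
#' correlation maximizes the bivariate-normal contingency-table
#' log-likelihood over `rho`. Estimates that run into the boundary are
#' clamped at `1 - 1e-6` in absolute value and flagged.
#'
#' @param x,y integer vectors in `0..K-1` (same length).
#' @param Kx,Ky category counts (defaults from the data).
#' @return list with `rho`, `thresholds_x`, `thresholds_y`, `table`,
#'   `clamped`, `loglik`.
#' @export
polychoric_pair <- function(x, y, Kx = max(x) + 1L, Ky = max(y) + 1L) {
  tx <- estimate_thresholds(x, Kx)
  ty <- estimate_thresholds(y, Ky)
  tab <- table(factor(tx$codes, levels = 0:(length(tx$levels) - 1L)),
               factor(ty$codes, levels = 0:(length(ty$levels) - 1L)))
  tab <- unclass(tab)
  fit <- poly_fit_rho(tab, tx$thresholds, ty$thresholds)
  c(fit, list(thresholds_x = tx$thresholds, thresholds_y = ty$thresholds,
              table = tab))
}

poly_fit_rho <- function(tab, tau_x, tau_y, eps = 1e-6) {
  nll <- function(rho) {
    P <- poly_cell_probs(tau_x, tau_y, rho)
    -sum(tab * log(pmax(P, 1e-300)))
  }
  opt <- optimize(nll, interval = c(-1 + eps, 1 - eps), tol = 1e-9)
  rho <- opt$minimum
  clamped <- abs(rho) > 1 - 1e-4
  if (clamped) rho <- sign(rho) * (1 - eps)
  list(rho = rho, loglik = -opt$objective, clamped = clamped)
}

#' Polychoric correlation matrix with asymptotic covariance
#'
#' Pairwise two-step estimates are assembled into a `p x p` matrix. If the
#' matrix is not positive definite it is smoothed by clipping eigenvalues at
#' `1e-6` and re-normalizing to unit diagonal (flagged). The asymptotic
#' covariance of the lower-triangle estimate vector is the influence-based
#' [acov_polychoric()] estimate.
#'
#' @param data `n x p` integer matrix, entries in `0..K-1`.
#' @param K category count (common to all items; default from the data).
#' @param acov compute the asymptotic covariance block? (needed by WLSMV)
#' @return object of class `"polychoric_result"`: list with `rho` (p x p),
#'   `thresholds` (per item), `gamma` (q x q asymptotic covariance of
#'   `sqrt(n) * s`, `q = p(p-1)/2`), `acov` (`gamma/n`), `n`,
#'   `collapsed` (per-item counts), `smoothed`, `clamped` (pair flags).
#' @export
polychoric_matrix <- function(data, K = max(data) + 1L, acov = TRUE) {
  p <- ncol(data)
  n <- nrow(data)
  marg <- vector("list", p)
  for (j in seq_len(p)) {
    marg[[j]] <- tryCatch(estimate_thresholds(data[, j], K),
                          error = function(e)
                            stop("column ", j, ": ", conditionMessage(e)))
  }
  q <- p * (p - 1L) / 2L
  R <- diag(p)
  clamped <- matrix(FALSE, p, p)
  pair_idx <- which(lower.tri(R), arr.ind = TRUE)
  pair_fits <- vector("list", q)
  for (idx in seq_len(q)) {
    i <- pair_idx[idx, 1]; j <- pair_idx[idx, 2]
    tab <- table(factor(marg[[j]]$codes, levels = 0:(length(marg[[j]]$levels) - 1L)),
                 factor(marg[[i]]$codes, levels = 0:(length(marg[[i]]$levels) - 1L)))
    tab <- unclass(tab)
    fit <- poly_fit_rho(tab, marg[[j]]$thresholds, marg[[i]]$thresholds)
    R[i, j] <- R[j, i] <- fit$rho
    clamped[i, j] <- clamped[j, i] <- fit$clamped
    pair_fits[[idx]] <- fit
  }
  sm <- smooth_correlation(R)
  out <- structure(list(rho = sm$R, rho_raw = R,
                        thresholds = lapply(marg, `[[`, "thresholds"),
                        margins = marg, n = n, K = K,
                        collapsed = vapply(marg, `[[`, 0L, "collapsed"),
                        smoothed = sm$smoothed,
                        clamped = clamped, pair_index = pair_idx),
                   class = "polychoric_result")
  if (acov) {
    out$gamma <- acov_polychoric(data, out)
    out$acov <- out$gamma / n
  }
  out
}

#' @export
print.polychoric_result <- function(x, ...) {
  cat(sprintf("Polychoric correlations: p = %d, n = %d%s\n",
              ncol(x$rho), x$n, if (x$smoothed) " (smoothed to PD)" else ""))
  print(round(x$rho, 3))
  invisible(x)
}

# derivative tables of the cell probabilities P(u, v) and of dP/drho with
# respect to one row-variable threshold tau_t (t in 1..r_a). Only the cell
# rows u = t and u = t + 1 are affected.
poly_cell_dtau <- function(tau_x, tau_y, rho, t) {
  s <- sqrt(1 - rho^2)
  by <- c(-Inf, tau_y, Inf)
  a <- tau_x[t]
  # conditional normal pieces at the boundary a
  Fy <- pnorm((by - rho * a) / s)
  colF <- diff(Fy)                           # length = ncols
  phi2 <- dbvnorm(a, by, rho)
  dphi_col <- -((a - rho * by) / (1 - rho^2)) * phi2
  dphi_col[!is.finite(by)] <- 0
  ddphi <- diff(dphi_col)
  nr <- length(tau_x) + 1L
  nc <- length(tau_y) + 1L
  dP <- matrix(0, nr, nc)
  dP[t, ] <- dnorm(a) * colF                 # cell row t gains mass
  dP[t + 1L, ] <- -dnorm(a) * colF           # row t+1 loses it
  dS <- matrix(0, nr, nc)                    # derivative of dP/drho
  dS[t, ] <- ddphi
  dS[t + 1L, ] <- -ddphi
  list(dP = dP, dS = dS)
}

#' Influence-based asymptotic covariance of polychoric estimates
#'
#' For each pair, the per-observation influence of the two-step estimate is
#' built from the score of the pairwise contingency-table log-likelihood at
#' the estimate, corrected for the sampling error of the step-1 threshold
#' estimates (whose own influence comes from the univariate cumulative
#' proportions), and divided by the average per-observation information.
#' `Gamma = crossprod(G)/n` then estimates the asymptotic covariance of
#' `sqrt(n)` times the lower-triangle correlation vector.
#'
#' @param data the ordinal data matrix used for estimation.
#' @param poly a [polychoric_matrix()] result.
#' @return `q x q` symmetric matrix, `q = p(p-1)/2` (lower-triangle order).
#' @export
acov_polychoric <- function(data, poly) {
  n <- nrow(data)
  q <- nrow(poly$pair_index)
  G <- matrix(0, n, q)
  for (idx in seq_len(q)) {
    i <- poly$pair_index[idx, 1]; j <- poly$pair_index[idx, 2]
    mi <- poly$margins[[j]]; mj <- poly$margins[[i]]   # (row var = j, col var = i)
    rho <- poly$rho_raw[i, j]
    P <- poly_cell_probs(mi$thresholds, mj$thresholds, rho)
    dP <- poly_cell_dprobs(mi$thresholds, mj$thresholds, rho)
    Psafe <- pmax(P, 1e-300)
    sc_cell <- dP / Psafe
    rows <- mi$codes + 1L; cols <- mj$codes + 1L
    sc <- sc_cell[cbind(rows, cols)]
    info <- mean(sc^2)
    if (info <= 0 || !is.finite(info))
      stop(sprintf("singular pairwise information for pair (%d, %d)", j, i))
    total <- sc
    # threshold-error correction: d(mean score)/d tau times the influence
    # of each estimated threshold (from the univariate margins)
    for (side in 1:2) {
      mm <- if (side == 1) mi else mj
      codes <- if (side == 1) rows else cols
      for (t_ in seq_along(mm$thresholds)) {
        d_ <- if (side == 1)
          poly_cell_dtau(mi$thresholds, mj$thresholds, rho, t_)
        else {
          tmp <- poly_cell_dtau(mj$thresholds, mi$thresholds, rho, t_)
          list(dP = t(tmp$dP), dS = t(tmp$dS))
        }
        dsc_cell <- (d_$dS * Psafe - dP * d_$dP) / Psafe^2
        Jt <- mean(dsc_cell[cbind(rows, cols)])
        pt <- pnorm(mm$thresholds[t_])
        psi <- ((codes <= t_) - pt) / dnorm(mm$thresholds[t_])
        total <- total + Jt * psi
      }
    }
    G[, idx] <- total / info
  }
  crossprod(G) / n
}

#' Influence-based asymptotic covariance of Pearson correlations
#'
#' Uses the influence function of the sample correlation,
#' `g_i = z_a z_b - r (z_a^2 + z_b^2) / 2`, on standardized scores. Returns
#' the asymptotic covariance of `sqrt(n)` times the lower-triangle
#' correlation vector, the Gamma matrix needed by the Satorra-Bentler
#' corrections for the normal-theory factor model.
#'
#' @param data numeric `n x p` matrix.
#' @return `q x q` matrix in lower-triangle order.
#' @export
acov_pearson <- function(data) {
  n <- nrow(data)
  p <- ncol(data)
  Z <- scale(data) * sqrt(n / (n - 1))   # population-style standardization
  R <- crossprod(Z) / n
  idx <- which(lower.tri(R), arr.ind = TRUE)
  G <- matrix(0, n, nrow(idx))
  for (k in seq_len(nrow(idx))) {
    a <- idx[k, 2]; b <- idx[k, 1]
    G[, k] <- Z[, a] * Z[, b] - R[a, b] * (Z[, a]^2 + Z[, b]^2) / 2
  }
  crossprod(G) / n
}

#' Normal-theory asymptotic covariance of sample correlations
#'
#' Closed-form `cov(sqrt(n) r_ij, sqrt(n) r_kl)` under multivariate
#' normality with population correlation matrix `R` (Olkin-Siotani), for the
#' lower-triangle correlation vector. This is the weight-matrix side of the
#' Satorra-Bentler correction for the ML factor model.
#'
#' @param R correlation matrix.
#' @return `q x q` matrix in lower-triangle order.
#' @export
nt_gamma_correlations <- function(R) {
  idx <- which(lower.tri(R), arr.ind = TRUE)
  q <- nrow(idx)
  G <- matrix(0, q, q)
  for (a in seq_len(q)) for (b in a:q) {
    i <- idx[a, 2]; j <- idx[a, 1]
    k <- idx[b, 2]; l <- idx[b, 1]
    v <- 0.5 * R[i, j] * R[k, l] *
      (R[i, k]^2 + R[i, l]^2 + R[j, k]^2 + R[j, l]^2) +
      R[i, k] * R[j, l] + R[i, l] * R[j, k] -
      R[i, j] * (R[j, k] * R[j, l] + R[i, k] * R[i, l]) -
      R[k, l] * (R[i, k] * R[j, k] + R[i, l] * R[j, l])
    G[a, b] <- G[b, a] <- v
  }
  G
}

# eigenvalue-clip smoothing to positive definiteness (unit diagonal kept)
smooth_correlation <- function(R, floor = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) > floor) return(list(R = R, smoothed = FALSE))
  v <- pmax(e$values, floor)
  S <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(S))
  S <- S / outer(d, d)
  diag(S) <- 1
  list(R = S, smoothed = TRUE)
}
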