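# ---- correlation-structure machinery shared by DWLS and the robust
# ---- corrections: model sigma(theta) = lower triangle of Lambda Lambda',
# ---- loadings in echelon form (upper-triangle zeros for identification).

theta_to_lambda <- function(theta, p, k) {
  L <- matrix(0, p, k)
  pos <- 1L
  for (m in seq_len(k)) {
    len <- p - m + 1L
    L[m:p, m] <- theta[pos:(pos + len - 1L)]
    pos <- pos + len
  }
  L
}

lambda_to_theta <- function(L) {
  k <- ncol(L); p <- nrow(L)
  unlist(lapply(seq_len(k), function(m) L[m:p, m]))
}

model_sigma_lower <- function(L) {
  S <- tcrossprod(L)
  S[lower.tri(S)]
}

# q x t Jacobian of the lower-triangle model correlations wrt free loadings
model_jacobian <- function(L) {
  p <- nrow(L); k <- ncol(L)
  idx <- which(lower.tri(diag(p)), arr.ind = TRUE)
  q <- nrow(idx)
  t_ <- efa_nfree(p, k)
  J <- matrix(0, q, t_)
  pos <- 0L
  for (m in seq_len(k)) {
    for (a in m:p) {
      pos <- pos + 1L
      ii <- idx[, 1]; jj <- idx[, 2]
      J[, pos] <- (ii == a) * L[jj, m] + (jj == a) * L[ii, m]
    }
  }
  J
}

#' Diagonally weighted least squares factor fit (WLSMV estimator)
#'
#' Fits the k-factor correlation structure to the polychoric correlations by
#' minimizing `(s - sigma(theta))' W^-1 (s - sigma(theta))` with
#' `W = diag(Gamma)`, the diagonal of the asymptotic covariance of the
#' estimated correlations. The unscaled statistic is `T = n * F_min`; it is
#' not chi-square distributed and is referred to the Satorra-Bentler
#' corrections ([mean_corrected_statistic()],
#' [mean_variance_corrected_statistic()]).
#'
#' @param poly a [polychoric_matrix()] result (with `gamma`).
#' @param k number of factors.
#' @return object of class `"fa_fit"` with `method = "DWLS"`, carrying the
#'   Jacobian, weights and `gamma` needed for the robust corrections.
#' @export
dwls_fit <- function(poly, k) {
  stopifnot(inherits(poly, "polychoric_result"))
  if (is.null(poly$gamma)) stop("polychoric result lacks the asymptotic covariance")
  R <- poly$rho
  p <- ncol(R)
  n <- poly$n
  df <- efa_df(p, k)
  s <- R[lower.tri(R)]
  w <- diag(poly$gamma)
  if (any(w <= 0)) stop("zero diagonal in Gamma at element ",
                        which(w <= 0)[1])
  ev <- eigen(R, symmetric = TRUE)
  L0 <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[seq_len(k)], 0.05)), k)
  h <- rowSums(L0^2)
  over <- h > 0.95
  if (any(over)) L0[over, ] <- L0[over, ] * sqrt(0.95 / h[over])
  for (m in seq_len(k)) if (m > 1) L0[seq_len(m - 1L), m] <- 0
  obj <- function(th) {
    r <- s - model_sigma_lower(theta_to_lambda(th, p, k))
    sum(r^2 / w)
  }
  grd <- function(th) {
    L <- theta_to_lambda(th, p, k)
    r <- s - model_sigma_lower(L)
    -2 * drop(crossprod(model_jacobian(L), r / w))
  }
  opt <- optim(lambda_to_theta(L0), obj, grd, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  L <- theta_to_lambda(opt$par, p, k)
  for (m in seq_len(k)) if (L[which.max(abs(L[, m])), m] < 0) L[, m] <- -L[, m]
  F_min <- max(opt$value, 0)
  T_stat <- n * F_min
  structure(list(k = k, loadings = L, uniquenesses = 1 - rowSums(L^2),
                 F_min = F_min, chisq = T_stat, df = df,
                 p_value = NA_real_,   # unscaled T has no chi-square reference
                 n = n, s = s, w = w, gamma = poly$gamma,
                 jacobian = model_jacobian(L),
                 R = R, method = "DWLS",
                 converged = opt$convergence == 0,
                 heywood = any(rowSums(L^2) >= 1)),
            class = "fa_fit")
}

# residual-projection matrix U = V - V D (D' V D)^-1 D' V for weight V
residual_u_matrix <- function(V, Delta) {
  VD <- V %*% Delta
  M <- crossprod(Delta, VD)
  Mi <- tryCatch(solve(M), error = function(e) solve(M + diag(1e-10, nrow(M))))
  V - VD %*% Mi %*% t(VD)
}

# weight matrix (as quadratic-form weight V) and Gamma for a fitted model
fit_correction_parts <- function(fit, gamma = NULL) {
  if (is.null(gamma)) gamma <- fit$gamma
  if (is.null(gamma)) stop("no asymptotic covariance (Gamma) available")
  Delta <- if (!is.null(fit$jacobian)) fit$jacobian else model_jacobian(fit$loadings)
  V <- if (fit$method == "DWLS") {
    diag(1 / fit$w)
  } else {
    # ML on a correlation matrix: normal-theory weight at the fitted structure
    Sig <- tcrossprod(fit$loadings) + diag(fit$uniquenesses)
    d <- sqrt(diag(Sig)); Sig <- Sig / outer(d, d)
    solve(nt_gamma_correlations(Sig) + diag(1e-10, nrow(Delta)))
  }
  list(V = V, Delta = Delta, gamma = gamma,
       U = residual_u_matrix(V, Delta))
}

#' Satorra-Bentler mean-corrected test statistic
#'
#' Rescales the test statistic so its mean matches the reference chi-square:
#' `c = trace(U Gamma) / df`, `T_M = T / c`, with `U` the residual-weight
#' projection of the estimator and `Gamma` the asymptotic covariance of the
#' sample correlations. When the data are well described by the estimator's
#' naive variance structure, `c` is close to 1 and `T_M` is close to `T`.
#'
#' @param fit an [ml_factor_fit()] or [dwls_fit()] result.
#' @param gamma optional `q x q` asymptotic covariance of `sqrt(n) * s`
#'   (defaults to the one stored in the fit).
#' @return list with `T_M`, `c`, `df`, `p_value`.
#' @export
mean_corrected_statistic <- function(fit, gamma = NULL) {
  parts <- fit_correction_parts(fit, gamma)
  df <- fit$df
  cc <- sum(diag(parts$U %*% parts$gamma)) / df
  if (!is.finite(cc) || cc <= 0) stop("pathological Gamma: scaling constant c <= 0")
  T_M <- fit$chisq / cc
  list(T_M = T_M, c = cc, df = df,
       p_value = pchisq(T_M, df, lower.tail = FALSE))
}

#' Satorra-Bentler style mean-and-variance corrected statistic
#'
#' Scale-and-shift correction matching the first two moments of the
#' statistic to the chi-square reference: with `t1 = trace(U Gamma)` and
#' `t2 = trace((U Gamma)^2)`, `a = sqrt(t2 / df)`, `b = df - t1 / a` and
#' `T_MV = T / a + b`. This is the statistic reported by the WLSMV
#' estimator.
#'
#' @inheritParams mean_corrected_statistic
#' @return list with `T_MV`, `a`, `b`, `df`, `p_value`.
#' @export
mean_variance_corrected_statistic <- function(fit, gamma = NULL) {
  parts <- fit_correction_parts(fit, gamma)
  df <- fit$df
  UG <- parts$U %*% parts$gamma
  t1 <- sum(diag(UG))
  t2 <- sum(UG * t(UG))
  if (!is.finite(t2) || t2 <= 0) stop("pathological Gamma: trace((U Gamma)^2) <= 0")
  a <- sqrt(t2 / df)
  b <- df - t1 / a
  T_MV <- fit$chisq / a + b
  list(T_MV = T_MV, a = a, b = b, df = df,
       p_value = pchisq(T_MV, df, lower.tail = FALSE))
}

#' Satorra-Bentler scaled chi-square difference test
#'
#' For nested fits with mean-scaling constants `c0`, `c1`, the scaled
#' difference is `dT_M = (T0 - T1) / c_d` with
#' `c_d = (c0 df0 - c1 df1) / (df0 - df1)`, referred to
#' `chi-square(df0 - df1)`. A non-positive `c_d` falls back to the unscaled
#' difference with a warning flag.
#'
#' @param T0,c0,df0 statistic, scaling and df of the restricted model.
#' @param T1,c1,df1 same for the less restricted model (`df1 < df0`).
#' @return list with `dT_M`, `df`, `p_value`, `c_d`, `fallback`.
#' @export
scaled_chisq_difference <- function(T0, c0, df0, T1, c1, df1) {
  if (df0 <= df1) stop("model 0 must be more restrictive (df0 > df1)")
  df_d <- df0 - df1
  c_d <- (c0 * df0 - c1 * df1) / df_d
  fallback <- FALSE
  if (!is.finite(c_d) || c_d <= 0) { c_d <- 1; fallback <- TRUE }
  dT <- max(T0 - T1, 0) / c_d
  list(dT_M = dT, df = df_d,
       p_value = pchisq(dT, df_d, lower.tail = FALSE),
       c_d = c_d, fallback = fallback)
}
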