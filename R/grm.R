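#' Graded response model category probabilities
#'
#' Cumulative-logit model: `P*(y >= t | theta) = plogis(a' theta - b_t)` for
#' `t = 1..K-1`, with `P*_0 = 1` and `P*_K = 0`; the category probability is
#' the difference of adjacent cumulative probabilities.
#'
#' @param params a `grm_params` object (or list with `slopes` p x k and
#'   `bounds` p x (K-1), bounds increasing per item).
#' @param item item index.
#' @param theta latent trait value(s): a k-vector, or a matrix with k
#'   columns for several points.
#' @return vector (or matrix, points x K) of category probabilities.
#' @export
grm_category_probs <- function(params, item, theta) {
  a <- params$slopes[item, ]
  b <- params$bounds[item, ]
  if (is.unsorted(b, strictly = TRUE)) stop("bounds must be strictly increasing")
  th <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1)
  eta <- outer(drop(th %*% a), b, `-`)
  Pstar <- cbind(1, plogis(eta), 0)
  P <- Pstar[, -ncol(Pstar), drop = FALSE] - Pstar[, -1, drop = FALSE]
  if (!is.matrix(theta)) drop(P) else P
}

# Gauss-Hermite nodes for N(0,1): Golub-Welsch via symmetric tridiagonal
gauss_hermite_normal <- function(nq) {
  i <- seq_len(nq - 1)
  J <- matrix(0, nq, nq)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = sqrt(2) * x[ord], weights = w[ord])
}

grm_quad_grid <- function(k, nq) {
  g1 <- gauss_hermite_normal(nq)
  if (k == 1) return(list(theta = matrix(g1$nodes, ncol = 1), w = g1$weights))
  grids <- rep(list(g1$nodes), k)
  th <- as.matrix(expand.grid(grids))
  dimnames(th) <- NULL
  wl <- rep(list(g1$weights), k)
  w <- Reduce(function(a, b) as.vector(outer(a, b)), wl)
  list(theta = th, w = w)
}

# expected complete-data negative log-likelihood and gradient for one item.
# Free parameters: free slopes, then (b1, log-increments). rmat is nq x K
# expected counts; theta nq x k; free = indices of free slopes.
grm_item_nll <- function(par, rmat, theta, K, free) {
  k <- ncol(theta)
  a <- numeric(k); a[free] <- par[seq_along(free)]
  bpar <- par[-seq_along(free)]
  b <- cumsum(c(bpar[1], exp(bpar[-1])))
  eta <- outer(drop(theta %*% a), b, `-`)
  Pstar <- cbind(1, plogis(eta), 0)
  P <- pmax(Pstar[, -(K + 1), drop = FALSE] - Pstar[, -1, drop = FALSE], 1e-300)
  -sum(rmat * log(P))
}

grm_item_grad <- function(par, rmat, theta, K, free) {
  k <- ncol(theta)
  a <- numeric(k); a[free] <- par[seq_along(free)]
  bpar <- par[-seq_along(free)]
  b <- cumsum(c(bpar[1], exp(bpar[-1])))
  eta <- outer(drop(theta %*% a), b, `-`)
  Ps <- plogis(eta)                       # nq x (K-1), t = 1..K-1
  Pstar <- cbind(1, Ps, 0)
  P <- pmax(Pstar[, -(K + 1), drop = FALSE] - Pstar[, -1, drop = FALSE], 1e-300)
  ratio <- rmat / P                       # nq x K
  # s_qt = Ps_t (1 - Ps_t) * (ratio[, t+1] - ratio[, t])  (category cols 1..K = 0..K-1)
  S <- Ps * (1 - Ps) * (ratio[, -1, drop = FALSE] - ratio[, -K, drop = FALSE])
  ga <- drop(crossprod(theta, rowSums(S)))[free]
  gb <- -colSums(S)                       # d LL / d b_t
  g1 <- sum(gb)
  gz <- if (K > 2) exp(bpar[-1]) * rev(cumsum(rev(gb)))[-1] else numeric(0)
  -c(ga, c(g1, gz))
}

#' Fit the graded response model by marginal maximum likelihood (EM)
#'
#' E-step: posterior weights of each (unique) response pattern over a
#' Gauss-Hermite grid (tensor product for `k >= 2`). M-step: per-item
#' maximization of the expected complete-data log-likelihood by BFGS on a
#' monotone parameterization of the category bounds. For `k >= 2` the model
#' is identified in echelon form (upper-triangle slopes fixed at zero).
#' Items with empty categories are collapsed (with a recorded mapping), so
#' the fit uses the categories observed in the sample.
#'
#' @param data `n x p` integer matrix, entries `0..K-1`.
#' @param k number of factors (1 or 2 are the intended sizes).
#' @param quad_points Gauss-Hermite points per dimension (default 21 for
#'   `k = 1`, 15 for `k = 2`).
#' @param tol EM convergence tolerance on the marginal log-likelihood.
#' @param max_iter maximum EM iterations.
#' @param init optional warm start: list with `slopes` (p x k) and `bounds`
#'   (p x (K-1), on the collapsed categories). Fitting the two-factor model
#'   from the one-factor solution keeps nested likelihoods ordered.
#' @return object of class `"grm_params"`: `slopes` (p x k, logit metric),
#'   `bounds` (p x (K-1), logit metric; `NA` for collapsed categories),
#'   `loglik`, `n_params`, `iterations`, `converged`, `category_maps`.
#' @export
grm_fit_em <- function(data, k = 1, quad_points = NULL, tol = 1e-5,
                       max_iter = 200L, init = NULL) {
  p <- ncol(data)
  n <- nrow(data)
  K <- max(data) + 1L
  if (is.null(quad_points)) quad_points <- if (k == 1) 21L else 15L
  if (k > 2) warning("k > 2: tensor quadrature will be slow")
  # collapse per-item empty categories
  maps <- vector("list", p)
  dat <- data
  Kj <- integer(p)
  for (j in seq_len(p)) {
    th <- estimate_thresholds(data[, j], K)
    dat[, j] <- th$codes
    maps[[j]] <- th$levels
    Kj[j] <- length(th$levels)
  }
  quad <- grm_quad_grid(k, quad_points)
  nq <- length(quad$w)
  # unique response patterns
  key <- apply(dat, 1, paste, collapse = ",")
  tab <- table(key)
  pat <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
  cnt <- as.numeric(tab)
  np <- nrow(pat)
  # parameters: start slopes 1 on factor 1, 0.5 elsewhere; bounds from margins
  D <- 1.702
  slopes <- matrix(0, p, k)
  slopes[, 1] <- 1
  if (k > 1) slopes[, 2:k] <- 0.5
  for (m in seq_len(k)) if (m > 1) slopes[seq_len(m - 1L), m] <- 0
  free_idx <- lapply(seq_len(p), function(j) {
    keep <- rep(TRUE, k)
    if (k > 1) for (m in 2:k) if (j < m) keep[m] <- FALSE
    which(keep)
  })
  bounds <- vector("list", p)
  for (j in seq_len(p)) {
    props <- tabulate(dat[, j] + 1L, nbins = Kj[j]) / n
    bounds[[j]] <- D * qnorm(cumsum(props)[-Kj[j]])
  }
  if (!is.null(init)) {
    sl <- as.matrix(init$slopes)
    got <- min(k, ncol(sl))
    slopes[, seq_len(got)] <- sl[, seq_len(got)]
    if (k > got) slopes[, (got + 1L):k] <- 0.1   # near the nested solution
    for (m in seq_len(k)) if (m > 1) slopes[seq_len(m - 1L), m] <- 0
    if (!is.null(init$bounds)) {
      bm <- as.matrix(init$bounds)
      for (j in seq_len(p)) {
        bj <- bm[j, !is.na(bm[j, ])]
        if (length(bj) == Kj[j] - 1L && !is.unsorted(bj, strictly = TRUE))
          bounds[[j]] <- bj
      }
    }
  }
  loglik_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step: log-likelihood of each pattern at each node
    logL <- matrix(0, np, nq)
    probs <- vector("list", p)
    for (j in seq_len(p)) {
      prm <- list(slopes = slopes[j, , drop = FALSE],
                  bounds = matrix(bounds[[j]], 1))
      P <- grm_category_probs(list(slopes = prm$slopes, bounds = prm$bounds),
                              1, quad$theta)
      if (is.null(dim(P))) P <- matrix(P, nrow = nq)
      probs[[j]] <- pmax(P, 1e-300)
      logL <- logL + t(log(probs[[j]])[, pat[, j] + 1L, drop = FALSE])
    }
    lw <- sweep(logL, 2, log(quad$w), `+`)
    mx <- apply(lw, 1, max)
    lik <- exp(lw - mx)
    marg <- rowSums(lik)
    ll <- sum(cnt * (log(marg) + mx))
    post <- lik / marg * cnt                # np x nq, weighted posteriors
    # M-step
    for (j in seq_len(p)) {
      rmat <- matrix(0, nq, Kj[j])
      for (c_ in seq_len(Kj[j]) - 1L) {
        sel <- pat[, j] == c_
        if (any(sel)) rmat[, c_ + 1L] <- colSums(post[sel, , drop = FALSE])
      }
      fr <- free_idx[[j]]
      b <- bounds[[j]]
      par0 <- c(slopes[j, fr], b[1], if (Kj[j] > 2) log(diff(b)))
      # slopes are boxed at |a| <= 8 (lambda ~ 0.98): quasi-separated items
      # otherwise send the slope to infinity along a flat likelihood ridge
      lo <- c(rep(-8, length(fr)), -30, rep(-10, max(Kj[j] - 2L, 0)))
      hi <- c(rep(8, length(fr)), 30, rep(5, max(Kj[j] - 2L, 0)))
      opt <- optim(pmin(pmax(par0, lo), hi), grm_item_nll, grm_item_grad,
                   rmat = rmat, theta = quad$theta, K = Kj[j], free = fr,
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 30))
      slopes[j, fr] <- opt$par[seq_along(fr)]
      bp <- opt$par[-seq_along(fr)]
      bounds[[j]] <- cumsum(c(bp[1], exp(bp[-1])))
    }
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol && ll - ll_old > -1e-6) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  bmat <- matrix(NA_real_, p, K - 1L)
  for (j in seq_len(p)) bmat[j, seq_len(Kj[j] - 1L)] <- bounds[[j]]
  n_par <- sum(lengths(free_idx)) + sum(Kj - 1L)
  structure(list(slopes = slopes, bounds = bmat, k = k, K = K,
                 loglik = ll_old, n_params = n_par,
                 iterations = length(loglik_trace),
                 loglik_trace = loglik_trace,
                 converged = converged,
                 category_maps = maps, n = n,
                 quad_points = quad_points),
            class = "grm_params")
}

#' @export
print.grm_params <- function(x, ...) {
  cat(sprintf("GRM fit: k = %d, K = %d, loglik = %.2f (%d EM iterations, %d parameters)\n",
              x$k, x$K, x$loglik, x$iterations, x$n_params))
  invisible(x)
}

#' Likelihood-ratio test between nested GRM fits
#'
#' @param fit_k,fit_k1 fits of the same data with `k` and `k + 1` factors.
#' @return list with `dif_G2`, `df`, `p_value`.
#' @export
grm_lrt <- function(fit_k, fit_k1) {
  if (fit_k1$n_params <= fit_k$n_params)
    stop("fits are not nested in the expected order")
  d <- 2 * (fit_k1$loglik - fit_k$loglik)
  if (d < -0.1) stop("likelihood decreased in the larger model: non-convergence")
  d <- max(d, 0)
  df <- fit_k1$n_params - fit_k$n_params
  list(dif_G2 = d, df = df, p_value = pchisq(d, df, lower.tail = FALSE))
}

#' Parameter counts for the GRM and the multidimensional nominal model
#'
#' GRM: `p*k - k(k-1)/2 + p*(K-1)` (slopes under echelon identification plus
#' category bounds). MNCM: `p*(k + (K-2) + (K-1)) - k(k-1)/2` (per-category
#' slopes with one category fixed, plus intercepts); the count is provided
#' for model-comparison bookkeeping, the MNCM itself is not fitted here.
#'
#' @param p items; `K` categories; `k` factors.
#' @param model `"GRM"` or `"MNCM"`.
#' @return integer parameter count.
#' @export
#' @examples
#' count_parameters(20, 6, 1, "GRM")   # 120
#' count_parameters(20, 6, 1, "MNCM")  # 200
count_parameters <- function(p, K, k, model = c("GRM", "MNCM")) {
  model <- match.arg(model)
  stopifnot(p >= 2, K >= 2, k >= 1)
  switch(model,
         GRM = p * k - k * (k - 1) / 2 + p * (K - 1),
         MNCM = p * (k + (K - 2) + (K - 1)) - k * (k - 1) / 2)
}

#' Convert IRT (logit) parameters to the factor-analytic parameterization
#'
#' With `a* = a / D` (`D = 1.702`, logit-to-probit),
#' `lambda_j = a*_j / sqrt(1 + ||a*_j||^2)` and
#' `tau_jt = (b_jt / D) / sqrt(1 + ||a*_j||^2)`.
#'
#' @param params a `grm_params` object (or list with `slopes`, `bounds`).
#' @param D logistic scaling constant.
#' @return list with `loadings` (p x k) and `thresholds` (p x (K-1)).
#' @export
irt_to_fa <- function(params, D = 1.702) {
  astar <- params$slopes / D
  denom <- sqrt(1 + rowSums(astar^2))
  list(loadings = astar / denom,
       thresholds = (params$bounds / D) / denom)
}

#' @rdname irt_to_fa
#' @param loadings p x k loading matrix with row norms < 1.
#' @param thresholds p x (K-1) threshold matrix.
#' @export
fa_to_irt <- function(loadings, thresholds, D = 1.702) {
  loadings <- as.matrix(loadings)
  scale <- 1 / sqrt(1 - rowSums(loadings^2))
  list(slopes = D * loadings * scale,
       bounds = D * as.matrix(thresholds) * scale)
}
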