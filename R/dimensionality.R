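#' Largest identified factor number
#'
#' The largest `k` with non-negative exploratory df (3 for `p = 6`,
#' 7 for `p = 12`).
#'
#' @param p number of variables.
#' @return integer.
#' @export
max_feasible_k <- function(p) {
  k <- 0L
  while (((p - k - 1)^2 - (p + k + 1)) / 2 >= 0) k <- k + 1L
  k
}

decision_record <- function(method, n_factors, p_value = NA_real_,
                            flag = "") {
  list(method = method, n_factors = n_factors,
       retained_one = !is.na(n_factors) && n_factors == 1L,
       p_value = p_value, flag = flag)
}

#' Sequential chi-square factor-number selection
#'
#' Fits `k = 1, 2, ...` and returns the smallest `k` whose test is
#' non-significant at `alpha` (the most parsimonious non-rejected model).
#' `method = "FA"` is normal-theory ML on the Pearson correlations,
#' `"FAC"` is the same ML discrepancy applied to the polychoric matrix
#' (the two-stage approximation in common use), and `"WLSMV"` is DWLS with
#' the mean-and-variance corrected statistic.
#'
#' @param data ordinal data matrix (integer categories).
#' @param method `"FA"`, `"FAC"` or `"WLSMV"`.
#' @param alpha decision level.
#' @param max_k largest k to try (default: largest identified k).
#' @param poly optional precomputed [polychoric_matrix()] (for `"FAC"` /
#'   `"WLSMV"`), to share work across methods.
#' @return decision record: list with `method`, `n_factors`,
#'   `retained_one`, `p_value` (of the one-factor test), `flag`.
#' @export
sequential_chisq_selection <- function(data, method = c("FA", "FAC", "WLSMV"),
                                       alpha = 0.05, max_k = NULL,
                                       poly = NULL) {
  method <- match.arg(method)
  p <- ncol(data)
  n <- nrow(data)
  if (is.null(max_k)) max_k <- max_feasible_k(p)
  if (method %in% c("FAC", "WLSMV") && is.null(poly))
    poly <- polychoric_matrix(data, acov = method == "WLSMV")
  R <- switch(method,
              FA = smooth_correlation(stats::cor(data))$R,
              FAC = poly$rho, WLSMV = NULL)
  p1 <- NA_real_
  flag <- ""
  for (k in seq_len(max_k)) {
    pv <- tryCatch({
      if (method == "WLSMV") {
        fit <- dwls_fit(poly, k)
        if (!fit$converged) flag <- paste(flag, "nonconv", sep = ";")
        if (fit$df == 0) 1 else mean_variance_corrected_statistic(fit)$p_value
      } else {
        fit <- ml_factor_fit(R, k, n)
        if (!fit$converged) flag <- paste(flag, "nonconv", sep = ";")
        fit$p_value
      }
    }, error = function(e) NA_real_)
    if (k == 1) p1 <- pv
    if (is.na(pv)) {
      flag <- paste(flag, sprintf("fit_error_k%d", k), sep = ";")
      next
    }
    if (pv > alpha)
      return(decision_record(method, k, p1, flag))
  }
  decision_record(method, max_k + 1L, p1, paste(flag, "cap_reached", sep = ";"))
}

#' One-factor retention by a 1-vs-2 factor difference test
#'
#' `method = "dTM"`: Satorra-Bentler scaled chi-square difference between
#' the one- and two-factor WLSMV fits. `method = "GRM"`: likelihood-ratio
#' test between one- and two-factor graded response models.
#'
#' @param data ordinal data matrix.
#' @param method `"dTM"` or `"GRM"`.
#' @param alpha decision level.
#' @param poly optional precomputed polychoric result (for `"dTM"`).
#' @param grm_quad quadrature points per dimension, length 2 (k = 1, k = 2).
#'   The two entries are kept equal by default: with matched grids the
#'   tensor quadrature of the two-factor model collapses exactly to the
#'   one-factor sum at zero second-factor slopes, so the warm-started
#'   nested likelihoods stay ordered and the difference test is clean.
#' @return decision record (`n_factors` is 1 or 2).
#' @export
retain_one_factor_difference <- function(data, method = c("dTM", "GRM"),
                                         alpha = 0.05, poly = NULL,
                                         grm_quad = c(15L, 15L)) {
  method <- match.arg(method)
  res <- tryCatch({
    if (method == "dTM") {
      if (is.null(poly)) poly <- polychoric_matrix(data)
      f1 <- dwls_fit(poly, 1)
      f2 <- dwls_fit(poly, 2)
      c1 <- mean_corrected_statistic(f1)
      c2 <- mean_corrected_statistic(f2)
      scaled_chisq_difference(f1$chisq, c1$c, f1$df,
                              f2$chisq, c2$c, f2$df)$p_value
    } else {
      f1 <- grm_fit_em(data, 1, quad_points = grm_quad[1])
      f2 <- grm_fit_em(data, 2, quad_points = grm_quad[2],
                       init = list(slopes = f1$slopes, bounds = f1$bounds))
      grm_lrt(f1, f2)$p_value
    }
  }, error = function(e) NA_real_)
  if (is.na(res))
    return(decision_record(method, NA_integer_, NA_real_, "fit_error"))
  decision_record(method, if (res > alpha) 1L else 2L, res)
}

#' Horn-style parallel analysis
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' chosen quantile of eigenvalues of null data obtained by independent
#' column-wise permutation of the observed values (which preserves the
#' marginals and applies unchanged to both correlation engines). The
#' indicated factor number is the count of leading observed eigenvalues
#' exceeding their null criterion, stopping at the first failure.
#'
#' @param data data matrix (ordinal or continuous).
#' @param engine `"pearson"` or `"polychoric"`.
#' @param n_resamples number of null resamples (>= 20).
#' @param criterion_quantile quantile of the null eigenvalue distribution.
#' @param seed optional seed for the permutations.
#' @return decision record with the indicated `n_factors`.
#' @export
parallel_analysis <- function(data, engine = c("pearson", "polychoric"),
                              n_resamples = 100L, criterion_quantile = 0.95,
                              seed = NULL) {
  engine <- match.arg(engine)
  if (n_resamples < 20) stop("use at least 20 resamples")
  if (!is.null(seed)) set.seed(seed)
  method <- if (engine == "pearson") "PA" else "CPA"
  corfun <- function(x) {
    if (engine == "pearson") stats::cor(x)
    else polychoric_matrix(x, acov = FALSE)$rho
  }
  flag <- ""
  obs <- tryCatch(eigen(corfun(data), symmetric = TRUE, only.values = TRUE)$values,
                  error = function(e) NULL)
  if (is.null(obs))
    return(decision_record(method, NA_integer_, NA_real_, "corr_error"))
  n <- nrow(data); p <- ncol(data)
  null_eig <- matrix(NA_real_, n_resamples, p)
  for (b in seq_len(n_resamples)) {
    perm <- apply(data, 2, sample)
    ev <- tryCatch(eigen(corfun(perm), symmetric = TRUE,
                         only.values = TRUE)$values,
                   error = function(e) rep(NA_real_, p))
    null_eig[b, ] <- ev
  }
  if (anyNA(null_eig)) {
    flag <- "null_degenerate"
    null_eig <- null_eig[stats::complete.cases(null_eig), , drop = FALSE]
  }
  crit <- apply(null_eig, 2, stats::quantile, probs = criterion_quantile)
  above <- obs > crit
  nf <- if (above[1]) which.min(c(above, FALSE)) - 1L else 0L
  decision_record(method, as.integer(nf), NA_real_, flag)
}

#' Empirical proportion of samples retaining the one-factor model
#'
#' The mean of the retention indicator over non-missing decision records;
#' `1 - eps` is the empirical Type-I error of the retention rule when the
#' generating model has one factor.
#'
#' @param decisions list of decision records (or a data frame with a
#'   `retained` / `retained_one` column).
#' @return list with `eps`, `n_effective`, `n_missing`, `mc_se`.
#' @export
eps <- function(decisions) {
  retained <- if (is.data.frame(decisions)) {
    col <- intersect(c("retained", "retained_one"), names(decisions))[1]
    decisions[[col]]
  } else {
    vapply(decisions, function(d) {
      if (is.na(d$n_factors)) NA else as.logical(d$retained_one)
    }, NA)
  }
  if (length(retained) == 0) stop("no decisions supplied")
  miss <- sum(is.na(retained))
  if (miss == length(retained)) stop("all decisions are missing")
  e <- mean(retained, na.rm = TRUE)
  n_eff <- length(retained) - miss
  list(eps = e, n_effective = n_eff, n_missing = miss,
       mc_se = sqrt(e * (1 - e) / n_eff))
}
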