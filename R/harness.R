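#' The full simulation condition grid
#'
#' Crossing sample size (100, 500), number of variables (6, 12), thresholds
#' (1, 2, 4), loading magnitude (0.6, 0.9) and skewness pattern (None, SP,
#' MM, SM, N+SM) gives 120 conditions.
#'
#' @param N,p,r,loading,skew_pattern level vectors (defaults = study grid).
#' @return data frame with one row per condition and a `condition_id`.
#' @export
condition_grid <- function(N = c(100L, 500L), p = c(6L, 12L),
                           r = c(1L, 2L, 4L), loading = c(0.6, 0.9),
                           skew_pattern = c("None", "SP", "MM", "SM", "N+SM")) {
  g <- expand.grid(N = N, p = p, r = r, loading = loading,
                   skew_pattern = skew_pattern,
                   stringsAsFactors = FALSE)
  g$condition_id <- sprintf("N%d_p%d_r%d_l%s_%s", g$N, g$p, g$r,
                            sub("0\\.", "", format(g$loading)), g$skew_pattern)
  g
}

derive_seed <- function(master_seed, cond, rep) {
  as.integer((as.numeric(master_seed) * 1000003 + cond * 10007 + rep * 101) %%
               2147483563) + 1L
}

#' Read a condition grid from a YAML or JSON configuration file
#'
#' The file holds the level vectors (`N`, `p`, `thresholds`, `loading`,
#' `skew_pattern`); missing keys fall back to the study defaults.
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return condition grid data frame.
#' @export
read_condition_grid <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(N = c(100L, 500L), p = c(6L, 12L), thresholds = c(1L, 2L, 4L),
                   loading = c(0.6, 0.9),
                   skew_pattern = c("None", "SP", "MM", "SM", "N+SM"))
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  condition_grid(N = cfg$N, p = cfg$p, r = cfg$thresholds,
                 loading = cfg$loading, skew_pattern = cfg$skew_pattern)
}

apply_methods_one <- function(dat, methods, alpha, pa_resamples,
                              pa_quantile, grm_quad, seed) {
  need_poly_acov <- any(c("WLSMV", "dTM") %in% methods)
  need_poly <- need_poly_acov || any(c("FAC", "CPA") %in% methods)
  poly <- NULL
  if (need_poly)
    poly <- tryCatch(polychoric_matrix(dat$data, acov = need_poly_acov),
                     error = function(e) NULL)
  out <- vector("list", length(methods))
  names(out) <- methods
  for (m in methods) {
    out[[m]] <- switch(m,
      FA = sequential_chisq_selection(dat$data, "FA", alpha),
      FAC = if (is.null(poly))
        decision_record("FAC", NA_integer_, NA_real_, "poly_error")
      else sequential_chisq_selection(dat$data, "FAC", alpha, poly = poly),
      WLSMV = if (is.null(poly))
        decision_record("WLSMV", NA_integer_, NA_real_, "poly_error")
      else sequential_chisq_selection(dat$data, "WLSMV", alpha, poly = poly),
      dTM = if (is.null(poly))
        decision_record("dTM", NA_integer_, NA_real_, "poly_error")
      else retain_one_factor_difference(dat$data, "dTM", alpha, poly = poly),
      GRM = retain_one_factor_difference(dat$data, "GRM", alpha,
                                         grm_quad = grm_quad),
      PA = parallel_analysis(dat$data, "pearson", pa_resamples, pa_quantile),
      CPA = parallel_analysis(dat$data, "polychoric", pa_resamples, pa_quantile),
      stop("unknown method: ", m))
  }
  list(decisions = out, poly = poly)
}

estimate_rows <- function(cond, rep, dat, poly, methods, grm_quad) {
  truth_l <- dat$truth$lambda
  truth_tau <- dat$truth$thresholds
  rows <- list()
  add <- function(method, lam, tau) {
    # align loading sign to truth before recording
    if (!is.null(lam) && sum(lam * truth_l) < 0) lam <- -lam
    p <- length(truth_l)
    df1 <- data.frame(condition_id = cond, replicate = rep, method = method,
                      item = seq_len(p), class = "lambda",
                      index = 1L, estimate = lam, truth = truth_l)
    df2 <- data.frame(condition_id = cond, replicate = rep, method = method,
                      item = seq_len(p), class = "psi",
                      index = 1L, estimate = 1 - lam^2, truth = 1 - truth_l^2)
    dfs <- list(df1, df2)
    if (!is.null(tau)) {
      r <- length(truth_tau[[1]])
      tmat <- if (is.matrix(tau)) tau else do.call(rbind, tau)
      for (t_ in seq_len(min(ncol(tmat), r))) {
        dfs[[length(dfs) + 1L]] <- data.frame(
          condition_id = cond, replicate = rep, method = method,
          item = seq_len(p), class = "tau", index = t_,
          estimate = tmat[, t_],
          truth = vapply(truth_tau, `[`, 0, t_))
      }
    }
    rows[[length(rows) + 1L]] <<- do.call(rbind, dfs)
  }
  if ("FA" %in% methods) {
    f <- tryCatch(ml_factor_fit(smooth_correlation(stats::cor(dat$data))$R, 1,
                                nrow(dat$data)), error = function(e) NULL)
    if (!is.null(f)) add("FA", drop(f$loadings), NULL)
  }
  if (!is.null(poly)) {
    if ("FAC" %in% methods) {
      f <- tryCatch(ml_factor_fit(poly$rho, 1, poly$n), error = function(e) NULL)
      if (!is.null(f)) add("FAC", drop(f$loadings),
                          do.call(rbind, lapply(poly$thresholds, function(x)
                            x[seq_len(min(lengths(poly$thresholds)))])))
    }
    if ("WLSMV" %in% methods) {
      f <- tryCatch(dwls_fit(poly, 1), error = function(e) NULL)
      if (!is.null(f)) add("WLSMV", drop(f$loadings),
                          do.call(rbind, lapply(poly$thresholds, function(x)
                            x[seq_len(min(lengths(poly$thresholds)))])))
    }
  }
  if ("GRM" %in% methods) {
    f <- tryCatch(grm_fit_em(dat$data, 1, quad_points = grm_quad[1]),
                  error = function(e) NULL)
    if (!is.null(f)) {
      fa <- irt_to_fa(f)
      add("GRM", drop(fa$loadings), fa$thresholds)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Run the Monte Carlo grid
#'
#' For each condition and replicate: generate a sample, apply the requested
#' factor-retention methods, and record the decision. Replicate seeds are
#' derived from `(master_seed, condition index, replicate index)` so any
#' replicate is reproducible in isolation; per-replicate failures are
#' recorded as flags and never abort the run.
#'
#' @param grid a [condition_grid()] (or subset of its rows).
#' @param methods subset of `c("FA","FAC","WLSMV","dTM","GRM","PA","CPA")`.
#' @param replicates samples per condition.
#' @param master_seed master seed.
#' @param alpha decision level for all tests.
#' @param pa_resamples,pa_quantile parallel-analysis settings.
#' @param grm_quad quadrature points for the GRM (k = 1, k = 2).
#' @param store_estimates record one-factor parameter estimates for
#'   [rmse_recovery()]?
#' @param progress print per-condition progress?
#' @return object of class `"sim_results"`: list with `decisions` (tidy data
#'   frame: condition fields, replicate, method, n_factors, retained,
#'   p_value, flag) and `estimates` (long data frame or NULL).
#' @export
run_grid <- function(grid, methods = c("FA", "PA"), replicates = 10L,
                     master_seed = 1L, alpha = 0.05,
                     pa_resamples = 100L, pa_quantile = 0.95,
                     grm_quad = c(15L, 15L),
                     store_estimates = FALSE, progress = FALSE) {
  res <- vector("list", nrow(grid) * replicates)
  est <- list()
  row_i <- 0L
  for (ci in seq_len(nrow(grid))) {
    cond <- grid[ci, ]
    if (progress)
      message(sprintf("[%d/%d] %s", ci, nrow(grid), cond$condition_id))
    for (rep_ in seq_len(replicates)) {
      seed <- derive_seed(master_seed, ci, rep_)
      dat <- generate_condition_sample(cond$N, cond$p, cond$r, cond$loading,
                                       skew_pattern = cond$skew_pattern,
                                       seed = seed)
      set.seed(seed + 1L)  # method-side randomness (PA permutations)
      ap <- apply_methods_one(dat, methods, alpha, pa_resamples,
                              pa_quantile, grm_quad, seed)
      for (m in methods) {
        d <- ap$decisions[[m]]
        row_i <- row_i + 1L
        res[[row_i]] <- data.frame(
          condition_id = cond$condition_id, N = cond$N, p = cond$p,
          r = cond$r, loading = cond$loading,
          skew_pattern = cond$skew_pattern, replicate = rep_,
          method = m, n_factors = d$n_factors,
          retained = if (is.na(d$n_factors)) NA else d$retained_one,
          p_value = d$p_value, flag = d$flag,
          stringsAsFactors = FALSE)
      }
      if (store_estimates) {
        er <- estimate_rows(cond$condition_id, rep_, dat, ap$poly,
                            methods, grm_quad)
        if (!is.null(er)) est[[length(est) + 1L]] <- er
      }
    }
  }
  structure(list(decisions = do.call(rbind, res[seq_len(row_i)]),
                 estimates = if (length(est)) do.call(rbind, est) else NULL,
                 methods = methods, replicates = replicates,
                 master_seed = master_seed, alpha = alpha),
            class = "sim_results")
}

#' @export
print.sim_results <- function(x, ...) {
  cat(sprintf("Simulation results: %d decision rows, methods: %s\n",
              nrow(x$decisions), paste(x$methods, collapse = ", ")))
  invisible(x)
}

#' EPS summary tables
#'
#' Aggregates the retention indicator into the empirical proportion of
#' samples retaining the one-factor model, by method and a grouping of the
#' condition fields. Preset layouts mirror the standard summaries: skewness
#' crossed with loading (`"skew_loading"`), with sample size (`"skew_N"`) or
#' with threshold count (`"skew_r"`), each within one level of `p`; every
#' row also carries the linear-model-true flag (patterns None and SP, where
#' all items share one threshold set).
#'
#' @param results a `sim_results` object (or its `decisions` data frame).
#' @param by character vector of grouping columns, or one of the presets
#'   `"skew_loading"`, `"skew_N"`, `"skew_r"`, `"overall"`.
#' @param p optional filter on the number of variables.
#' @return data frame with grouping keys, `method`, `eps`, `n_effective`,
#'   `n_missing`, `mc_se`.
#' @export
summarize_eps <- function(results, by = "overall", p = NULL) {
  d <- if (inherits(results, "sim_results")) results$decisions else results
  if (!nrow(d)) stop("empty results")
  if (!is.null(p)) d <- d[d$p == p, , drop = FALSE]
  if (length(by) == 1 && by %in% c("skew_loading", "skew_N", "skew_r", "overall")) {
    by <- switch(by,
                 skew_loading = c("skew_pattern", "loading"),
                 skew_N = c("skew_pattern", "N"),
                 skew_r = c("skew_pattern", "r"),
                 overall = character(0))
  }
  bad <- setdiff(by, names(d))
  if (length(bad)) stop("unknown grouping key(s): ", paste(bad, collapse = ", "))
  d$linear_model <- d$skew_pattern %in% c("None", "SP")
  keys <- c("linear_model", by, "method")
  keys <- keys[!duplicated(keys)]
  if (!length(by)) keys <- "method"
  split_keys <- interaction(d[keys], drop = TRUE, lex.order = TRUE)
  parts <- split(d, split_keys)
  out <- do.call(rbind, lapply(parts, function(g) {
    e <- eps(g)
    cbind(g[1, keys, drop = FALSE],
          data.frame(eps = e$eps, n_effective = e$n_effective,
                     n_missing = e$n_missing, mc_se = e$mc_se))
  }))
  rownames(out) <- NULL
  out[order(out$method), , drop = FALSE]
}

#' Factorial ANOVA effect sizes for the logit p-value
#'
#' Fits a fixed-effects factorial ANOVA to `logit(p)` (p-values clamped to
#' `[1e-12, 1 - 1e-12]`) for one method's decisions, and reports the partial
#' eta-squared `SS_effect / (SS_effect + SS_error)` per term.
#'
#' @param results `sim_results` (or decisions data frame).
#' @param method which method's p-values to analyze.
#' @param factors condition fields entering the design.
#' @param max_interaction_order highest interaction order fitted.
#' @return data frame with `term`, `df`, `ss`, `partial_eta2`, ordered by
#'   effect size.
#' @export
anova_partial_eta <- function(results, method = "FA",
                              factors = c("N", "p", "r", "loading",
                                          "skew_pattern"),
                              max_interaction_order = 2L) {
  d <- if (inherits(results, "sim_results")) results$decisions else results
  d <- d[d$method == method & !is.na(d$p_value), , drop = FALSE]
  if (!nrow(d)) stop("no p-values recorded for method ", method)
  factors <- factors[vapply(factors, function(f) length(unique(d[[f]])) > 1,
                            NA)]
  eps_ <- 1e-12
  pv <- pmin(pmax(d$p_value, eps_), 1 - eps_)
  d$logit_p <- log(pv / (1 - pv))
  for (f in factors) d[[f]] <- factor(d[[f]])
  fml <- stats::as.formula(paste("logit_p ~ (",
                                 paste(factors, collapse = " + "),
                                 ")^", max_interaction_order))
  fit <- stats::aov(fml, data = d)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  ss <- tab[["Sum Sq"]]
  err <- ss[terms == "Residuals"]
  keep <- terms != "Residuals"
  denom <- ss[keep] + err
  out <- data.frame(term = terms[keep], df = tab[["Df"]][keep],
                    ss = ss[keep],
                    partial_eta2 = ifelse(denom > 0, ss[keep] / denom, 0))
  out[order(-out$partial_eta2), , drop = FALSE]
}

#' Parameter-recovery RMSE
#'
#' Root mean squared error between true and estimated one-factor parameters
#' (loadings `lambda`, uniquenesses `psi`, thresholds `tau`), per condition,
#' method and parameter class, pooled over items and replicates. Loading
#' signs are aligned to the truth before the error is taken (the GRM
#' estimates are converted to the factor-analytic metric at collection
#' time).
#'
#' @param results `sim_results` run with `store_estimates = TRUE`.
#' @return data frame with `condition_id`, `method`, `class`, `rmse`, `n`.
#' @export
rmse_recovery <- function(results) {
  est <- if (inherits(results, "sim_results")) results$estimates else results
  if (is.null(est) || !nrow(est))
    stop("no stored estimates: run the grid with store_estimates = TRUE")
  est <- est[!is.na(est$estimate), , drop = FALSE]
  keys <- interaction(est$condition_id, est$method, est$class,
                      drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(est, keys), function(g) {
    data.frame(condition_id = g$condition_id[1], method = g$method[1],
               class = g$class[1],
               rmse = sqrt(mean((g$estimate - g$truth)^2)),
               n = nrow(g))
  }))
  rownames(out) <- NULL
  out
}
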