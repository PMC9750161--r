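#' Generator specification for one-factor categorical data
#'
#' @param n sample size (>= 1).
#' @param p number of items (>= 2).
#' @param r number of thresholds per item (K = r + 1 categories).
#' @param lambda common loading magnitude, in (0, 1).
#' @param gamma_per_item vector of `p` skewness targets.
#' @param seed integer seed driving the sample.
#' @return object of class `"generator_spec"`.
#' @export
generator_spec <- function(n, p, r, lambda, gamma_per_item, seed = 1L) {
  stopifnot(n >= 1, p >= 2, r >= 1)
  if (lambda <= 0 || lambda >= 1)
    stop("lambda must lie in (0, 1) so the error variance 1 - lambda^2 is positive")
  if (length(gamma_per_item) != p)
    stop("gamma_per_item must have length p")
  structure(list(n = as.integer(n), p = as.integer(p), r = as.integer(r),
                 lambda = lambda, gamma_per_item = as.numeric(gamma_per_item),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Latent continuous responses under the one-factor model
#'
#' Draws `y*_ij = lambda_j * xi_i + e_ij` with `xi ~ N(0,1)` and
#' `e_ij ~ N(0, 1 - lambda_j^2)`, so each latent response has unit variance
#' and the thresholds live on the standard-normal scale. The population
#' correlation of any two columns is `lambda_i * lambda_j`.
#'
#' @param spec a [generator_spec()].
#' @return `n x p` numeric matrix.
#' @export
generate_latent <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  lam <- rep_len(spec$lambda, spec$p)
  xi <- rnorm(spec$n)
  e <- matrix(rnorm(spec$n * spec$p), spec$n, spec$p)
  sweep(e, 2, sqrt(1 - lam^2), `*`) + outer(xi, lam)
}

#' Discretize latent responses at per-item thresholds
#'
#' The observed category is the number of thresholds strictly below the
#' latent value: `y = k` iff `tau_k < y* <= tau_{k+1}` with `tau_0 = -Inf`.
#'
#' @param latent `n x p` numeric matrix.
#' @param thresholds list of `p` [thresholds_from_gamma()] results, or a
#'   list of plain numeric threshold vectors.
#' @return `n x p` integer matrix with entries in `0..r`.
#' @export
discretize <- function(latent, thresholds) {
  p <- ncol(latent)
  if (length(thresholds) != p) stop("need one threshold set per column")
  out <- matrix(0L, nrow(latent), p)
  for (j in seq_len(p)) {
    tau <- thresholds[[j]]
    if (inherits(tau, "threshold_set")) tau <- tau$thresholds
    out[, j] <- as.integer(findInterval(latent[, j], tau, left.open = TRUE))
  }
  out
}

#' Generate an ordinal dataset for one simulation condition
#'
#' Builds per-item thresholds from the skewness targets, draws the latent
#' one-factor sample and discretizes it. The returned object stores the
#' exact generating parameters (`truth`).
#'
#' @param n,p,r,lambda,seed see [generator_spec()].
#' @param skew_pattern pattern name passed to [skew_pattern_gammas()];
#'   ignored when `gamma_per_item` is given.
#' @param gamma_per_item optional explicit skewness targets.
#' @param keep_latent retain the latent matrix in the result?
#' @return object of class `"ordinal_dataset"`: list with `data` (integer
#'   matrix, categories `0..r`), `truth` (spec, thresholds, loadings) and
#'   optionally `latent`.
#' @export
#' @examples
#' d <- generate_condition_sample(200, 6, 1, 0.6, skew_pattern = "SM", seed = 7)
#' table(d$data[, 1])
generate_condition_sample <- function(n, p, r, lambda,
                                      skew_pattern = "None",
                                      gamma_per_item = NULL,
                                      seed = 1L, keep_latent = FALSE) {
  if (is.null(gamma_per_item))
    gamma_per_item <- skew_pattern_gammas(skew_pattern, p)
  spec <- generator_spec(n, p, r, lambda, gamma_per_item, seed)
  tsets <- lapply(unique(gamma_per_item), thresholds_from_gamma, r = r)
  names(tsets) <- as.character(unique(gamma_per_item))
  thresholds <- lapply(as.character(gamma_per_item), function(g) tsets[[g]])
  latent <- generate_latent(spec)
  data <- discretize(latent, thresholds)
  out <- list(data = data,
              truth = list(spec = spec,
                           lambda = rep_len(lambda, p),
                           gamma = gamma_per_item,
                           thresholds = lapply(thresholds, `[[`, "thresholds")))
  if (keep_latent) out$latent <- latent
  structure(out, class = "ordinal_dataset")
}

#' @export
print.ordinal_dataset <- function(x, ...) {
  s <- x$truth$spec
  cat(sprintf("Ordinal dataset: n = %d, p = %d, K = %d categories, lambda = %g\n",
              s$n, s$p, s$r + 1L, s$lambda))
  cat("gamma:", x$truth$gamma, "\n")
  invisible(x)
}

#' Write / read an ordinal dataset as CSV plus JSON sidecar
#'
#' The data matrix goes to a headered CSV of integer categories; the
#' generating truth (loadings, skewness targets, thresholds, seed) goes to
#' `<path>.json`.
#'
#' @param x an `ordinal_dataset`.
#' @param path CSV file path.
#' @return `write_ordinal_dataset` returns `path` invisibly;
#'   `read_ordinal_dataset` returns an `ordinal_dataset`.
#' @export
write_ordinal_dataset <- function(x, path) {
  stopifnot(inherits(x, "ordinal_dataset"))
  df <- as.data.frame(x$data)
  names(df) <- paste0("item", seq_len(ncol(df)))
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(spec = unclass(x$truth$spec),
                  lambda = x$truth$lambda,
                  gamma = x$truth$gamma,
                  thresholds = x$truth$thresholds)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ordinal_dataset
#' @export
read_ordinal_dataset <- function(path) {
  df <- utils::read.csv(path)
  data <- as.matrix(df)
  dimnames(data) <- NULL
  storage.mode(data) <- "integer"
  truth <- NULL
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    j <- jsonlite::read_json(sc, simplifyVector = TRUE)
    spec <- generator_spec(j$spec$n, j$spec$p, j$spec$r, j$spec$lambda,
                           j$spec$gamma_per_item, j$spec$seed)
    truth <- list(spec = spec, lambda = j$lambda, gamma = j$gamma,
                  thresholds = if (is.list(j$thresholds)) j$thresholds
                               else as.list(as.data.frame(t(j$thresholds))))
  }
  structure(list(data = data, truth = truth), class = "ordinal_dataset")
}
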