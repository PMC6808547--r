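#' Fit and apply a z-transform
#'
#' Stores each column's mean and sample SD (n - 1 denominator) from the fit
#' set so that new calls can later be projected with the same constants.
#'
#' @param x numeric matrix or data frame of per-call parameters (>= 2 rows).
#' @return A list with `center`, `scale` and `apply(newdata)`; class
#'   `zscore_fit`.
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 rows to z-scale", call. = FALSE)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  bad <- which(scale == 0 | !is.finite(scale))
  if (length(bad)) {
    stop("constant column(s): ",
         paste(colnames(x)[bad] %||% bad, collapse = ", "), call. = FALSE)
  }
  structure(list(center = center, scale = scale), class = "zscore_fit")
}

#' @rdname zscore_fit
#' @param fit a `zscore_fit`.
#' @param newdata matrix or data frame with the fit's columns.
#' @export
zscore_apply <- function(fit, newdata) {
  stopifnot(inherits(fit, "zscore_fit"))
  x <- as.matrix(newdata)
  if (!is.null(colnames(x)) && !is.null(names(fit$center))) {
    missing <- setdiff(names(fit$center), colnames(x))
    if (length(missing)) {
      stop("newdata is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    x <- x[, names(fit$center), drop = FALSE]
  }
  sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
}

#' Horn parallel-analysis eigenvalue thresholds
#'
#' For each eigenvalue rank, the chosen quantile (default 95%) of that
#' rank's correlation-matrix eigenvalue across `n_iter` standard-normal
#' datasets of the same shape as the empirical data. Components whose
#' observed eigenvalue exceeds the threshold at their rank are considered
#' to carry more structure than sampling noise alone produces.
#'
#' @param n_rows,n_cols shape of the empirical data (`n_rows > n_cols >= 2`).
#' @param n_iter number of random datasets (default 10000, the convention
#'   of the analysis this package implements).
#' @param quantile quantile of the null eigenvalue distribution.
#' @param seed RNG seed; thresholds are deterministic given the seed.
#' @return Numeric vector of per-rank thresholds (length `n_cols`), with
#'   the call parameters as attributes.
#' @export
parallel_analysis_thresholds <- function(n_rows, n_cols, n_iter = 10000,
                                         quantile = 0.95, seed = 1L) {
  if (!(n_rows > n_cols && n_cols >= 2)) {
    stop("need n_rows > n_cols >= 2", call. = FALSE)
  }
  if (n_iter < 100) {
    warning("n_iter < 100 gives unstable eigenvalue quantiles")
  }
  eig <- with_seed(seed, {
    e <- matrix(0, n_iter, n_cols)
    for (i in seq_len(n_iter)) {
      x <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
      e[i, ] <- eigen(stats::cor(x), symmetric = TRUE,
                      only.values = TRUE)$values
    }
    e
  })
  thr <- apply(eig, 2, stats::quantile, probs = quantile, names = FALSE)
  attr(thr, "n_rows") <- n_rows
  attr(thr, "n_iter") <- n_iter
  attr(thr, "quantile") <- quantile
  attr(thr, "seed") <- as.integer(seed)
  thr
}

#' Principal components with parallel-analysis retention
#'
#' Z-transforms the parameter table, performs PCA on the correlation
#' structure, and retains the leading run of components whose eigenvalue
#' exceeds its rank's parallel-analysis threshold (retention stops at the
#' first non-exceeding rank, so the retained set has no gaps). A scalar
#' mode compares every eigenvalue against the rank-1 threshold instead.
#' Loadings have orthonormal columns with a fixed sign convention (the
#' largest-magnitude loading of each component is positive) so repeated
#' runs are identical.
#'
#' @param x numeric matrix or data frame of per-call parameters.
#' @param thresholds per-rank thresholds from
#'   [parallel_analysis_thresholds()]; computed with `n_iter` and `seed`
#'   when missing.
#' @param n_iter,quantile,seed passed to [parallel_analysis_thresholds()]
#'   when `thresholds` is missing.
#' @param mode `"rankwise"` (classic Horn, default) or `"scalar"`.
#' @param call_type optional label carried on the model.
#' @return A `retained_pca`: z-scaling constants, loading matrix
#'   (parameters x retained components), all eigenvalues, explained
#'   -variance proportions (of the total variance), and `n_retained`.
#'   Errors when no component passes the threshold.
#' @export
retained_pca <- function(x, thresholds = NULL, n_iter = 10000,
                         quantile = 0.95, seed = 1L,
                         mode = c("rankwise", "scalar"),
                         call_type = NA_character_) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  zfit <- zscore_fit(x)
  z <- zscore_apply(zfit, x)
  p <- ncol(z)
  if (is.null(thresholds)) {
    thresholds <- parallel_analysis_thresholds(nrow(z), p, n_iter = n_iter,
                                               quantile = quantile,
                                               seed = seed)
  }
  if (length(thresholds) != p) {
    stop("thresholds length does not match the number of parameters",
         call. = FALSE)
  }
  ed <- eigen(stats::cor(z), symmetric = TRUE)
  eigenvalues <- ed$values
  exceeds <- if (mode == "rankwise") eigenvalues > thresholds
             else eigenvalues > thresholds[1]
  n_retained <- if (exceeds[1]) which.min(c(exceeds, FALSE)) - 1L else 0L
  if (n_retained == 0L) {
    stop(paste("no component exceeds its parallel-analysis threshold;",
               "the data show no retainable structure (consider a scalar",
               "threshold mode or pooling more calls)"), call. = FALSE)
  }
  loadings <- ed$vectors[, seq_len(n_retained), drop = FALSE]
  for (k in seq_len(n_retained)) {   # sign convention for reproducibility
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) loadings[, k] <- -loadings[, k]
  }
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- paste0("PC", seq_len(n_retained))
  structure(list(
    center = zfit$center,
    scale = zfit$scale,
    loadings = loadings,
    eigenvalues = eigenvalues,
    proportions = eigenvalues / p,
    n_retained = n_retained,
    thresholds = as.numeric(thresholds),
    mode = mode,
    call_type = call_type,
    n_fit = nrow(z)
  ), class = "retained_pca")
}

#' @export
print.retained_pca <- function(x, ...) {
  cat(sprintf("retained_pca%s: %d of %d components retained\n",
              if (is.na(x$call_type)) "" else paste0(" [", x$call_type, "]"),
              x$n_retained, length(x$eigenvalues)))
  prop <- 100 * x$proportions[seq_len(x$n_retained)]
  cat(sprintf("  eigenvalues: %s\n",
              paste(sprintf("%.3f", x$eigenvalues[seq_len(x$n_retained)]),
                    collapse = ", ")))
  cat(sprintf("  explained variance: %s (cumulative %.1f%%)\n",
              paste(sprintf("%.1f%%", prop), collapse = ", "), sum(prop)))
  invisible(x)
}

#' Project calls into retained component space
#'
#' Applies the stored z-scaling constants and multiplies by the retained
#' loadings. Projecting the fit set reproduces the fit scores.
#'
#' @param object a `retained_pca`.
#' @param newdata matrix or data frame with the model's parameter columns.
#' @param ... unused.
#' @return Score matrix (rows x retained components).
#' @export
predict.retained_pca <- function(object, newdata, ...) {
  z <- zscore_apply(structure(list(center = object$center,
                                   scale = object$scale),
                              class = "zscore_fit"), newdata)
  z %*% object$loadings
}

#' Serialize a retained-PCA model to JSON
#'
#' Versioned plain-text serialization of scaling constants, loadings,
#' eigenvalues and proportions.
#'
#' @param model a `retained_pca`.
#' @param path file path.
#' @return `read_pca_model()` returns the `retained_pca`.
#' @export
write_pca_model <- function(model, path) {
  stopifnot(inherits(model, "retained_pca"))
  x <- unclass(model)
  x$format_version <- 1L
  x$param_names <- rownames(model$loadings)
  x$loadings <- as.vector(model$loadings)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  loadings <- matrix(x$loadings, ncol = x$n_retained)
  rownames(loadings) <- x$param_names
  colnames(loadings) <- paste0("PC", seq_len(x$n_retained))
  structure(list(
    center = stats::setNames(x$center, x$param_names),
    scale = stats::setNames(x$scale, x$param_names),
    loadings = loadings,
    eigenvalues = x$eigenvalues,
    proportions = x$proportions,
    n_retained = as.integer(x$n_retained),
    thresholds = x$thresholds,
    mode = x$mode,
    call_type = x$call_type,
    n_fit = x$n_fit
  ), class = "retained_pca")
}
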