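#' Principal component analysis of a spectral matrix
#'
#' Columns are mean-centred (no variance scaling, the convention for
#' intensity matrices) and the top `k` principal axes are extracted by
#' singular value decomposition. The sign of each loading column is fixed so
#' that its largest-magnitude element is positive, making results
#' reproducible across runs and platforms.
#'
#' @param x Numeric matrix (n_samples x n_points) or a [sers_set()].
#' @param k Number of components, `k <= min(n_samples - 1, n_points)`.
#' @return A list of class `pca_model` with elements `mean` (column means),
#'   `loadings` (n_points x k, orthonormal columns),
#'   `explained_variance_ratio` (length k, fractions of total variance),
#'   `scores` (training scores, n_samples x k) and `k`.
#' @export
fit_pca <- function(x, k = 2L) {
  X <- if (inherits(x, "sers_set")) x$matrix else as.matrix(x)
  if (any(!is.finite(X))) stop("matrix must be finite", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (k < 1L || k > min(n - 1L, p)) {
    stop("k must satisfy 1 <= k <= min(n_samples - 1, n_points)",
         call. = FALSE)
  }
  total_var <- sum(apply(X, 2L, stats::var))
  if (total_var <= 0) {
    stop("matrix has zero variance; PCA undefined", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| element of each column positive
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- sweep(X, 2L, pc$center) %*% load
  structure(list(mean = pc$center, loadings = load,
                 explained_variance_ratio = pc$sdev[seq_len(k)]^2 / total_var,
                 scores = scores, k = k),
            class = "pca_model")
}

#' Project new data onto a fitted PCA model
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param x Numeric matrix or [sers_set()] with the same number of points as
#'   the training data.
#' @return An n x k score matrix.
#' @export
pca_transform <- function(model, x) {
  X <- if (inherits(x, "sers_set")) x$matrix else as.matrix(x)
  if (ncol(X) != length(model$mean)) {
    stop("column count does not match the fitted model", call. = FALSE)
  }
  sweep(X, 2L, model$mean) %*% model$loadings
}

#' Write PCA loadings and scores as CSV for plotting
#'
#' @param model A `pca_model`.
#' @param path_prefix Output stem; writes `<prefix>_loadings.csv`
#'   (wavenumber + one column per PC) and `<prefix>_scores.csv`.
#' @param axis Optional wavenumber axis for the loadings table.
#' @return The two paths written, invisibly.
#' @export
pca_export <- function(model, path_prefix, axis = NULL) {
  ld <- as.data.frame(model$loadings)
  names(ld) <- paste0("PC", seq_len(model$k))
  if (!is.null(axis)) ld <- cbind(`wavenumber_cm-1` = axis, ld)
  p1 <- paste0(path_prefix, "_loadings.csv")
  utils::write.csv(ld, p1, row.names = FALSE, quote = FALSE)
  sc <- as.data.frame(model$scores)
  names(sc) <- paste0("PC", seq_len(model$k))
  p2 <- paste0(path_prefix, "_scores.csv")
  utils::write.csv(sc, p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
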