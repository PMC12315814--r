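#' Shapley values for one query sample
#'
#' Attributes the deviation of `model_fn(x_query)` from the mean model
#' output over a background set to individual features, using the
#' interventional (marginal) convention: absent features are imputed from
#' background rows. `mode = "exact"` enumerates all feature subsets
#' (allowed up to 12 features); `mode = "sampled"` averages marginal
#' contributions over seeded random feature orderings, one background row
#' per ordering.
#'
#' @param model_fn Function mapping a numeric matrix (rows = samples) to a
#'   numeric score vector.
#' @param background Non-empty background sample matrix.
#' @param x_query Numeric query vector, `length == ncol(background)`.
#' @param mode `"exact"` or `"sampled"`.
#' @param n_perm Number of permutations in sampled mode.
#' @param seed Integer seed (sampled mode).
#' @param feature_ids Optional feature identifiers (e.g. wavenumbers);
#'   defaults to `colnames(background)` or indices.
#' @return A list of class `shapley_explanation` with `phi` (named numeric
#'   vector), `baseline` (mean background output), `fx`
#'   (`model_fn(x_query)`), `feature_ids`, `mode`, and in sampled mode `se`,
#'   the per-feature Monte-Carlo standard error. Efficiency
#'   `sum(phi) = fx - baseline` holds to 1e-6 in exact mode.
#' @export
shapley_values <- function(model_fn, background, x_query,
                           mode = c("sampled", "exact"), n_perm = 1000L,
                           seed = 1L, feature_ids = NULL) {
  mode <- match.arg(mode)
  background <- as.matrix(background)
  p <- ncol(background)
  if (nrow(background) < 1L) stop("background must be non-empty",
                                  call. = FALSE)
  if (length(x_query) != p) {
    stop("x_query length must match background columns", call. = FALSE)
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(background)
    if (is.null(feature_ids)) feature_ids <- as.character(seq_len(p))
  }
  baseline <- mean(model_fn(background))
  fx <- as.numeric(model_fn(matrix(x_query, 1L)))
  if (mode == "exact") {
    if (p > 12L) {
      stop("exact mode is limited to 12 features; use mode = 'sampled'",
           call. = FALSE)
    }
    phi <- shapley_exact(model_fn, background, x_query, p)
    se <- NULL
  } else {
    est <- shapley_sampled(model_fn, background, x_query, p, n_perm, seed)
    phi <- est$phi; se <- est$se
  }
  names(phi) <- feature_ids
  structure(list(phi = phi, baseline = baseline, fx = fx,
                 feature_ids = feature_ids, mode = mode, se = se),
            class = "shapley_explanation")
}

shapley_exact <- function(model_fn, background, x_query, p) {
  nbg <- nrow(background)
  nset <- 2L^p
  masks <- matrix(FALSE, nset, p)
  for (i in seq_len(p)) {
    masks[, i] <- bitwAnd(0:(nset - 1L), 2L^(i - 1L)) > 0L
  }
  # value of every coalition: mean over background rows of the mixed sample
  v <- numeric(nset)
  big <- matrix(0, nset * nbg, p)
  for (b in seq_len(nbg)) {
    rows <- (b - 1L) * nset + seq_len(nset)
    z <- matrix(background[b, ], nset, p, byrow = TRUE)
    z[masks] <- matrix(x_query, nset, p, byrow = TRUE)[masks]
    big[rows, ] <- z
  }
  fv <- model_fn(big)
  v <- rowMeans(matrix(fv, nset, nbg))
  sizes <- rowSums(masks)
  wts <- factorial(0:(p - 1L)) * factorial(p - 1L - (0:(p - 1L))) /
    factorial(p)
  phi <- numeric(p)
  for (i in seq_len(p)) {
    without <- which(!masks[, i])
    with_ <- without + 2L^(i - 1L)
    phi[i] <- sum(wts[sizes[without] + 1L] * (v[with_] - v[without]))
  }
  phi
}

shapley_sampled <- function(model_fn, background, x_query, p, n_perm, seed) {
  nbg <- nrow(background)
  contrib <- matrix(0, n_perm, p)
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      ord <- sample.int(p)
      b <- background[sample.int(nbg, 1L), ]
      # progressive coalition matrix: row k has features ord[1..k-1] from
      # the query, the rest from the background row
      Z <- matrix(b, p + 1L, p, byrow = TRUE)
      for (k in seq_len(p)) {
        Z[(k + 1L):(p + 1L), ord[k]] <- x_query[ord[k]]
      }
      fz <- model_fn(Z)
      contrib[r, ord] <- diff(fz)
    }
  })
  list(phi = colMeans(contrib),
       se = apply(contrib, 2L, stats::sd) / sqrt(n_perm))
}

#' Rank features by mean absolute Shapley value
#'
#' The per-sample absolute values are averaged across explanations (not the
#' absolute value of the mean), then sorted descending; ties are broken by
#' ascending feature id.
#'
#' @param explanations List of `shapley_explanation` objects sharing one
#'   feature set.
#' @return A data.frame with columns `feature`, `mean_abs_phi`, ordered by
#'   decreasing importance.
#' @export
shapley_summary <- function(explanations) {
  stopifnot(length(explanations) >= 1L)
  ids <- explanations[[1L]]$feature_ids
  for (e in explanations) {
    if (!identical(e$feature_ids, ids)) {
      stop("explanations have mismatched feature sets", call. = FALSE)
    }
  }
  absmat <- do.call(rbind, lapply(explanations, function(e) abs(e$phi)))
  m <- colMeans(absmat)
  num_ids <- suppressWarnings(as.numeric(ids))
  tie_key <- if (anyNA(num_ids)) xtfrm(ids) else num_ids
  ord <- order(-m, tie_key)
  data.frame(feature = ids[ord], mean_abs_phi = unname(m[ord]))
}

#' Partial-dependence curve for one feature
#'
#' `PDP(v) = mean over rows x of model_fn(x with the feature set to v)`:
#' the model's average response as the feature is varied with all others
#' held at their observed values.
#'
#' @param model_fn Function mapping a matrix to a score vector.
#' @param X Non-empty sample matrix.
#' @param feature Column index of the feature to vary.
#' @param grid Strictly increasing feature values; values outside the
#'   observed range trigger a warning (extrapolation).
#' @return A list of class `pdp_curve` with `feature`, `grid` and `mean_score`.
#' @export
partial_dependence <- function(model_fn, X, feature, grid) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("X must be non-empty", call. = FALSE)
  if (any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  rng <- range(X[, feature])
  if (any(grid < rng[1L] - 1e-12) || any(grid > rng[2L] + 1e-12)) {
    warning("grid extends beyond the observed feature range (extrapolation)")
  }
  mean_score <- vapply(grid, function(v) {
    Z <- X
    Z[, feature] <- v
    mean(model_fn(Z))
  }, 0)
  structure(list(feature = feature, grid = grid, mean_score = mean_score),
            class = "pdp_curve")
}

#' Spectrum-level score function of a PCA + binary SVM pipeline
#'
#' Wraps a PCA projection followed by a binary SVM score so a model trained
#' on principal-component scores can be interrogated (Shapley values,
#' partial dependence) in the original wavenumber feature view.
#'
#' @param pca A `pca_model` from [fit_pca()].
#' @param svm A binary `svm_model` trained on the PCA scores.
#' @return Function mapping a spectra matrix to decision scores.
#' @export
spectral_score_fn <- function(pca, svm) {
  function(M) svm_predict(svm, pca_transform(pca, as.matrix(M)))$scores
}
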