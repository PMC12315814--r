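#' SVM configuration
#'
#' @param kernel `"linear"` or `"gaussian"`.
#' @param box_constraint Box constraint C > 0 (upper bound on every dual
#'   coefficient).
#' @param kernel_scale Kernel scale s > 0; every feature is divided by s
#'   before inner products are taken (for both kernels).
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(kernel = c("linear", "gaussian"), box_constraint = 1,
                       kernel_scale = 1) {
  kernel <- match.arg(kernel)
  if (box_constraint <= 0 || kernel_scale <= 0) {
    stop("box_constraint and kernel_scale must be positive", call. = FALSE)
  }
  structure(list(kernel = kernel, box_constraint = box_constraint,
                 kernel_scale = kernel_scale),
            class = "svm_config")
}

#' Gram matrix between two sample sets
#'
#' @param X,Z Numeric matrices (rows = samples) with equal column counts.
#' @param config An [svm_config()]; features are divided by its
#'   `kernel_scale` first. Linear: `u . v`; Gaussian: `exp(-|u - v|^2)`.
#' @return The `nrow(X)` x `nrow(Z)` Gram matrix.
#' @export
kernel_matrix <- function(X, Z, config) {
  U <- as.matrix(X) / config$kernel_scale
  V <- as.matrix(Z) / config$kernel_scale
  if (config$kernel == "linear") {
    U %*% t(V)
  } else {
    d2 <- outer(rowSums(U^2), rep(1, nrow(V))) +
      outer(rep(1, nrow(U)), rowSums(V^2)) - 2 * U %*% t(V)
    exp(-pmax(d2, 0))
  }
}

# Binary SMO on a precomputed Gram matrix. Maximal-violating-pair working
# set selection; maintains f_i = sum_j alpha_j y_j K_ij. Stops when the
# violating-pair gap (in score units) drops below tol.
smo_binary <- function(K, y, C, tol = 1e-3, max_iter = 20000L) {
  n <- length(y)
  alpha <- numeric(n)
  f <- numeric(n)               # score without bias
  it <- 0L
  repeat {
    E <- f - y
    up <- (y > 0 & alpha < C - 1e-12 * C) | (y < 0 & alpha > 1e-12 * C)
    lo <- (y > 0 & alpha > 1e-12 * C) | (y < 0 & alpha < C - 1e-12 * C)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.min(E[up])]
    # second-order selection of the partner: maximal objective gain
    cand <- which(lo & E > E[i] + 1e-15)
    if (!length(cand)) break
    eta_all <- pmax(K[i, i] + diag(K)[cand] - 2 * K[cand, i], 1e-12)
    gain <- (E[cand] - E[i])^2 / (2 * eta_all)
    j <- cand[which.max(gain)]
    gap <- max(E[lo]) - E[i]
    if (gap <= tol || it >= max_iter) break
    it <- it + 1L
    eta <- max(K[i, i] + K[j, j] - 2 * K[i, j], 1e-12)
    a_j_old <- alpha[j]; a_i_old <- alpha[i]
    if (y[i] != y[j]) {
      L <- max(0, a_j_old - a_i_old); H <- min(C, C + a_j_old - a_i_old)
    } else {
      L <- max(0, a_i_old + a_j_old - C); H <- min(C, a_i_old + a_j_old)
    }
    a_j <- a_j_old + y[j] * (E[i] - E[j]) / eta
    a_j <- min(max(a_j, L), H)
    if (abs(a_j - a_j_old) < 1e-15 * max(1, C)) break
    a_i <- a_i_old + y[i] * y[j] * (a_j_old - a_j)
    alpha[i] <- a_i; alpha[j] <- a_j
    f <- f + (a_i - a_i_old) * y[i] * K[, i] + (a_j - a_j_old) * y[j] * K[, j]
  }
  E <- f - y
  up <- (y > 0 & alpha < C - 1e-12 * C) | (y < 0 & alpha > 1e-12 * C)
  lo <- (y > 0 & alpha > 1e-12 * C) | (y < 0 & alpha < C - 1e-12 * C)
  kkt_gap <- if (any(up) && any(lo)) max(0, max(E[lo]) - min(E[up])) else 0
  free <- alpha > 1e-8 * C & alpha < C * (1 - 1e-8)
  b <- if (any(free)) mean(y[free] - f[free]) else {
    -(max(E[lo]) + min(E[up])) / 2
  }
  list(alpha = alpha, b = b, f = f, kkt_gap = kkt_gap, iterations = it)
}

#' Train a soft-margin SVM by sequential minimal optimization
#'
#' Solves the dual problem
#' `max sum(alpha) - 1/2 sum alpha_i alpha_j y_i y_j G(x_i, x_j)` subject to
#' `0 <= alpha <= C` and `sum(alpha * y) = 0`, by pairwise coordinate ascent
#' on the maximal violating pair. Multiclass input is handled one-vs-one
#' with majority voting.
#'
#' @param X Feature matrix (rows = samples) or [sers_set()].
#' @param y Class labels (character/factor), two or more classes.
#' @param config An [svm_config()].
#' @param tol Stopping tolerance on the violating-pair gap, in score units.
#' @param max_iter Maximum number of pair updates.
#' @return A list of class `svm_model`. Binary models carry `alphas`,
#'   `support_indices`, `bias`, `labels_pm1`, `training_vectors`, `config`,
#'   `class_names` (first name is the +1 class) and `kkt_gap`; multiclass
#'   models carry `pairs`, a list of binary models, plus `class_names`.
#' @export
train_svm <- function(X, y, config = svm_config(), tol = 1e-3,
                      max_iter = 20000L) {
  if (inherits(X, "sers_set")) {
    if (missing(y)) y <- X$labels
    X <- X$matrix
  }
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    stop("training data must contain at least two classes", call. = FALSE)
  }
  if (length(classes) == 2L) {
    return(train_svm_binary(X, y, classes, config, tol, max_iter))
  }
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    keep <- y %in% pr
    train_svm_binary(X[keep, , drop = FALSE], y[keep], pr, config, tol,
                     max_iter)
  })
  structure(list(pairs = fits, class_names = classes, config = config),
            class = c("svm_model_multi", "svm_model"))
}

train_svm_binary <- function(X, y, classes, config, tol, max_iter) {
  ypm <- ifelse(y == classes[1L], 1, -1)
  K <- kernel_matrix(X, X, config)
  sol <- smo_binary(K, ypm, config$box_constraint, tol, max_iter)
  sv <- which(sol$alpha > 1e-8 * config$box_constraint)
  structure(list(alphas = sol$alpha, support_indices = sv, bias = sol$b,
                 labels_pm1 = ypm, training_vectors = X, config = config,
                 class_names = classes, kkt_gap = sol$kkt_gap,
                 iterations = sol$iterations),
            class = c("svm_model_binary", "svm_model"))
}

#' Dual objective value of a trained binary SVM
#'
#' `sum(alpha) - 1/2 * t(alpha * y) G (alpha * y)` on the training Gram
#' matrix; the quantity SMO maximizes.
#'
#' @param model A binary `svm_model`.
#' @return Scalar objective value.
#' @export
svm_dual_objective <- function(model) {
  stopifnot(inherits(model, "svm_model_binary"))
  K <- kernel_matrix(model$training_vectors, model$training_vectors,
                     model$config)
  ay <- model$alphas * model$labels_pm1
  sum(model$alphas) - 0.5 * as.numeric(t(ay) %*% K %*% ay)
}

#' Score and classify new samples with a trained SVM
#'
#' Binary: `score(z) = sum_j alpha_j y_j G(x_j, z) + b`, class by sign (a
#' score of exactly 0 goes to the +1 class, which is the first class name).
#' Multiclass: one score column per class pair, classes by majority vote
#' with ties broken toward the smallest class index.
#'
#' @param model An `svm_model`.
#' @param Z Feature matrix or [sers_set()] with the training column count.
#' @return A list with `scores` (vector for binary, matrix with one column
#'   per pair otherwise) and `classes` (character vector).
#' @export
svm_predict <- function(model, Z) {
  if (inherits(Z, "sers_set")) Z <- Z$matrix
  Z <- as.matrix(Z)
  if (inherits(model, "svm_model_binary")) {
    if (ncol(Z) != ncol(model$training_vectors)) {
      stop("feature dimension does not match training data", call. = FALSE)
    }
    s <- svm_score_binary(model, Z)
    cls <- ifelse(s >= 0, model$class_names[1L], model$class_names[2L])
    return(list(scores = s, classes = cls))
  }
  votes <- matrix(0L, nrow(Z), length(model$class_names),
                  dimnames = list(NULL, model$class_names))
  scores <- matrix(NA_real_, nrow(Z), length(model$pairs))
  nm <- character(length(model$pairs))
  for (p in seq_along(model$pairs)) {
    fit <- model$pairs[[p]]
    s <- svm_score_binary(fit, Z)
    scores[, p] <- s
    nm[p] <- paste(fit$class_names, collapse = "|")
    win <- ifelse(s >= 0, fit$class_names[1L], fit$class_names[2L])
    for (k in model$class_names) votes[win == k, k] <- votes[win == k, k] + 1L
  }
  colnames(scores) <- nm
  cls <- model$class_names[apply(votes, 1L, which.max)]
  list(scores = scores, classes = cls, votes = votes)
}

svm_score_binary <- function(model, Z) {
  if (ncol(Z) != ncol(model$training_vectors)) {
    stop("feature dimension does not match training data", call. = FALSE)
  }
  ay <- model$alphas * model$labels_pm1
  keep <- ay != 0
  if (!any(keep)) return(rep(model$bias, nrow(Z)))
  K <- kernel_matrix(Z, model$training_vectors[keep, , drop = FALSE],
                     model$config)
  as.numeric(K %*% ay[keep]) + model$bias
}

#' k-fold cross-validated misclassification rate
#'
#' Samples are shuffled into `folds` disjoint folds under the seed; each
#' fold is scored by an SVM trained on the remaining folds and the pooled
#' misclassification fraction is returned. A fold whose training part
#' degenerates to a single class is dropped with a warning.
#'
#' @param X Feature matrix or [sers_set()].
#' @param y Class labels (defaults to the set's labels).
#' @param config An [svm_config()].
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @param tol,max_iter Passed to [train_svm()].
#' @return Misclassification fraction in \[0, 1\], with the per-sample fold
#'   assignment attached as attribute `"folds"`.
#' @export
cv_loss <- function(X, y = NULL, config = svm_config(), folds = 5L,
                    seed = 1L, tol = 1e-3, max_iter = 20000L) {
  if (inherits(X, "sers_set")) {
    if (is.null(y)) y <- X$labels
    X <- X$matrix
  }
  X <- as.matrix(X); y <- as.character(y)
  n <- nrow(X)
  if (folds < 2L || n < folds) {
    stop("need folds >= 2 and at least one sample per fold", call. = FALSE)
  }
  assign_ <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  wrong <- 0L; total <- 0L
  for (k in seq_len(folds)) {
    tr <- assign_ != k
    if (length(unique(y[tr])) < 2L) {
      warning("fold ", k, " dropped: training part has a single class")
      next
    }
    fit <- train_svm(X[tr, , drop = FALSE], y[tr], config, tol, max_iter)
    pred <- svm_predict(fit, X[!tr, , drop = FALSE])$classes
    wrong <- wrong + sum(pred != y[!tr])
    total <- total + sum(!tr)
  }
  if (total == 0L) stop("no fold could be evaluated", call. = FALSE)
  structure(wrong / total, folds = assign_)
}

#' Platt calibration of binary SVM scores
#'
#' Fits `p(y = +1 | s) = 1 / (1 + exp(-(A s + B)))` by maximum likelihood
#' with Platt's smoothed targets `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)`,
#' which regularize the fit on separable data.
#'
#' @param model A binary `svm_model`.
#' @param X Feature matrix (defaults to the model's training vectors).
#' @param y Class labels (defaults to the training labels).
#' @return A list of class `platt_calibration` with elements `A` and `B`.
#' @export
platt_calibrate <- function(model, X = NULL, y = NULL) {
  stopifnot(inherits(model, "svm_model_binary"))
  if (is.null(X)) X <- model$training_vectors
  s <- svm_score_binary(model, as.matrix(X))
  pos <- if (is.null(y)) model$labels_pm1 > 0 else {
    as.character(y) == model$class_names[1L]
  }
  platt_fit(s, pos)
}

#' @rdname platt_calibrate
#' @param scores Numeric decision scores.
#' @param positive Logical vector: `TRUE` for the +1 class.
#' @export
platt_fit <- function(scores, positive) {
  s <- scores
  pos <- positive
  if (all(pos) || !any(pos)) {
    stop("calibration requires both classes", call. = FALSE)
  }
  np <- sum(pos); nn <- sum(!pos)
  t_ <- ifelse(pos, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    z <- par[1L] * s + par[2L]
    # stable log(1 + exp(z)) and cross-entropy against soft targets
    sum((1 - t_) * z + log1p(exp(-abs(z))) + pmax(z, 0) - z)
  }
  grad <- function(par) {
    p <- stats::plogis(par[1L] * s + par[2L])
    c(sum((p - t_) * s), sum(p - t_))
  }
  fit <- stats::optim(c(1, 0), nll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  structure(list(A = fit$par[1L], B = fit$par[2L]),
            class = "platt_calibration")
}

#' Posterior probabilities from a Platt calibration
#'
#' @param calibration A `platt_calibration`.
#' @param scores Numeric vector of decision scores.
#' @return Probabilities of the +1 (first-named) class, in (0, 1).
#' @export
platt_predict <- function(calibration, scores) {
  stats::plogis(calibration$A * scores + calibration$B)
}

#' Serialize a trained SVM to JSON
#'
#' Writes dual coefficients, support vectors, bias, signed labels and the
#' kernel configuration; multiclass models are written as a list of pairwise
#' binary models. [read_svm_model()] restores a model that predicts
#' identically.
#'
#' @param model An `svm_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_svm_model <- function(model, path) {
  ser_bin <- function(m) {
    list(alphas = m$alphas, support_indices = m$support_indices,
         bias = m$bias, labels_pm1 = m$labels_pm1,
         training_vectors = m$training_vectors,
         config = unclass(m$config), class_names = m$class_names,
         kkt_gap = m$kkt_gap)
  }
  obj <- if (inherits(model, "svm_model_binary")) {
    c(ser_bin(model), list(type = "binary"))
  } else {
    list(type = "one_vs_one", class_names = model$class_names,
         config = unclass(model$config),
         pairs = lapply(model$pairs, ser_bin))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(v) as.numeric(unlist(v))
  deser_bin <- function(o) {
    cfg <- svm_config(o$config$kernel, o$config$box_constraint,
                      o$config$kernel_scale)
    tv <- do.call(rbind, lapply(o$training_vectors, num))
    structure(list(alphas = num(o$alphas),
                   support_indices = as.integer(unlist(o$support_indices)),
                   bias = o$bias, labels_pm1 = num(o$labels_pm1),
                   training_vectors = tv,
                   config = cfg,
                   class_names = as.character(unlist(o$class_names)),
                   kkt_gap = o$kkt_gap),
              class = c("svm_model_binary", "svm_model"))
  }
  if (identical(obj$type, "binary")) return(deser_bin(obj))
  cfg <- svm_config(obj$config$kernel, obj$config$box_constraint,
                    obj$config$kernel_scale)
  structure(list(pairs = lapply(obj$pairs, deser_bin),
                 class_names = as.character(unlist(obj$class_names)),
                 config = cfg),
            class = c("svm_model_multi", "svm_model"))
}
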