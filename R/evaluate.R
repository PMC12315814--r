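# half-up decimal rounding for reported percentages; raw fractions are kept
# alongside so rounding never feeds downstream computation
round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Split a dataset into training, validation and test sets
#'
#' The pooled set (not each class separately) is shuffled under the seed and
#' cut into `round(n * f)` training and validation samples, with the test
#' set absorbing the rounding remainder. Non-stratified by default; with
#' `stratified = TRUE` the same rule is applied within each class.
#'
#' @param set A [sers_set()] with at least 10 spectra.
#' @param fractions Positive `(train, val, test)` fractions summing to 1.
#' @param seed Integer seed.
#' @param stratified Split within each class instead of the pooled set.
#' @return A named list of three [sers_set()] objects: `train`, `val`,
#'   `test`; pairwise disjoint by sample id and exhaustive.
#' @export
split_dataset <- function(set, fractions = c(0.6, 0.1, 0.3), seed = 1L,
                          stratified = FALSE) {
  stopifnot(inherits(set, "sers_set"))
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be three positive numbers summing to 1",
         call. = FALSE)
  }
  n <- n_spectra(set)
  if (n < 10L) stop("need at least 10 spectra to split", call. = FALSE)
  cut3 <- function(idx, seed_) {
    m <- length(idx)
    ord <- with_seed(seed_, sample(idx))
    n_tr <- round(m * fractions[1L])
    n_va <- round(m * fractions[2L])
    n_te <- m - n_tr - n_va
    if (n_tr < 1L || n_va < 1L || n_te < 1L) {
      stop("a split would receive 0 samples; adjust fractions or n",
           call. = FALSE)
    }
    list(train = ord[seq_len(n_tr)],
         val = ord[n_tr + seq_len(n_va)],
         test = ord[n_tr + n_va + seq_len(n_te)])
  }
  if (!stratified) {
    parts <- cut3(seq_len(n), seed)
  } else {
    classes <- unique(set$labels)
    per <- lapply(seq_along(classes), function(k) {
      cut3(which(set$labels == classes[k]),
           (as.numeric(seed) * 31 + k) %% 2147483647)
    })
    parts <- list(train = unlist(lapply(per, `[[`, "train")),
                  val = unlist(lapply(per, `[[`, "val")),
                  test = unlist(lapply(per, `[[`, "test")))
  }
  lapply(parts, function(i) set[i])
}

#' Classification metrics from true and predicted labels
#'
#' Builds the d x d confusion matrix (rows = true class, columns =
#' predicted) and per-class recall and precision in percent, plus overall
#' accuracy. Reported percentages are rounded half-up to one decimal; the
#' raw fractions are kept in `*_raw` fields. A class absent from `y_true`
#' has undefined recall, reported as `NA` (not 0).
#'
#' @param y_true,y_pred Equal-length label vectors; every label must be in
#'   `class_order`.
#' @param class_order Character vector fixing row/column order.
#' @return A list of class `evaluation_metrics`: `confusion`, `recall`,
#'   `precision`, `overall_accuracy` (percent, 1 decimal), and raw
#'   fractions.
#' @export
evaluate <- function(y_true, y_pred, class_order = sort(unique(y_true))) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (!all(c(y_true, y_pred) %in% class_order)) {
    stop("labels outside class_order", call. = FALSE)
  }
  f <- factor(y_true, levels = class_order)
  g <- factor(y_pred, levels = class_order)
  cm <- table(true = f, predicted = g)
  cm <- matrix(as.integer(cm), nrow = length(class_order),
               dimnames = list(true = class_order, predicted = class_order))
  rec_raw <- stats::setNames(
    ifelse(rowSums(cm) > 0, diag(cm) / rowSums(cm), NA_real_), class_order)
  pre_raw <- stats::setNames(
    ifelse(colSums(cm) > 0, diag(cm) / colSums(cm), NA_real_), class_order)
  acc_raw <- sum(diag(cm)) / length(y_true)
  structure(list(
    confusion = cm,
    recall = round_half_up(100 * rec_raw),
    precision = round_half_up(100 * pre_raw),
    overall_accuracy = round_half_up(100 * acc_raw),
    recall_raw = rec_raw, precision_raw = pre_raw,
    accuracy_raw = acc_raw, n = length(y_true),
    class_order = class_order),
    class = "evaluation_metrics")
}

#' ROC curve and AUC for binary scores
#'
#' The ROC is swept over all score thresholds and the AUC computed by the
#' trapezoidal rule, which equals the probability that a random positive
#' outscores a random negative with ties counted one half (the Mann-Whitney
#' statistic). Higher scores must indicate the positive class.
#'
#' @param scores Numeric score vector.
#' @param y_true Binary labels.
#' @param positive The positive class label; defaults to the last sorted
#'   level.
#' @return A list with `roc` (data.frame of `fpr`, `tpr` swept over
#'   thresholds) and `auc`.
#' @export
roc_auc <- function(scores, y_true, positive = NULL) {
  y_true <- as.character(y_true)
  lv <- sort(unique(y_true))
  if (length(lv) != 2L) {
    stop("roc_auc requires exactly two classes in y_true", call. = FALSE)
  }
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (is.null(positive)) positive <- lv[2L]
  negative <- setdiff(lv, positive)
  r <- pROC::roc(response = factor(y_true, levels = c(negative, positive)),
                 predictor = scores, direction = "<", quiet = TRUE)
  list(roc = data.frame(fpr = rev(1 - r$specificities),
                        tpr = rev(r$sensitivities)),
       auc = as.numeric(r$auc))
}

#' One-vs-rest AUC per class
#'
#' @param score_matrix n x d matrix of per-class scores (columns named by
#'   class).
#' @param y_true Label vector.
#' @return Named numeric vector of per-class AUC values.
#' @export
roc_auc_ovr <- function(score_matrix, y_true) {
  classes <- colnames(score_matrix)
  stats::setNames(vapply(classes, function(k) {
    roc_auc(score_matrix[, k], ifelse(y_true == k, k, "rest"),
            positive = k)$auc
  }, 0), classes)
}

#' Assemble a full evaluation report
#'
#' Confusion matrix and class metrics, plus per-class one-vs-rest ROC/AUC
#' when scores are supplied and an optional cross-validation loss.
#'
#' @param y_true,y_pred Label vectors.
#' @param class_order Class order for the confusion matrix.
#' @param score_matrix Optional n x d per-class score matrix for ROC/AUC.
#' @param cv_loss Optional cross-validated misclassification fraction.
#' @return A list of class `evaluation_report`.
#' @export
evaluation_report <- function(y_true, y_pred,
                              class_order = sort(unique(y_true)),
                              score_matrix = NULL, cv_loss = NULL) {
  metrics <- evaluate(y_true, y_pred, class_order)
  auc <- roc <- NULL
  if (!is.null(score_matrix)) {
    score_matrix <- as.matrix(score_matrix)
    if (is.null(colnames(score_matrix))) {
      colnames(score_matrix) <- class_order
    }
    auc <- roc_auc_ovr(score_matrix, y_true)
    roc <- lapply(stats::setNames(colnames(score_matrix),
                                  colnames(score_matrix)), function(k) {
      roc_auc(score_matrix[, k], ifelse(y_true == k, k, "rest"),
              positive = k)$roc
    })
  }
  structure(c(unclass(metrics), list(auc = auc, roc = roc,
                                     cv_loss = cv_loss)),
            class = "evaluation_report")
}

#' Write / read an evaluation report as JSON
#'
#' The JSON round-trips losslessly: numbers are written at full precision.
#'
#' @param report An `evaluation_report`.
#' @param path JSON path.
#' @return `path` invisibly; `read_report()` returns the restored report.
#' @export
write_report <- function(report, path) {
  obj <- unclass(report)
  obj$confusion <- list(classes = report$class_order,
                        counts = unname(report$confusion))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  classes <- obj$confusion$classes
  cm <- matrix(as.integer(obj$confusion$counts), length(classes),
               dimnames = list(true = classes, predicted = classes))
  out <- obj
  out$confusion <- cm
  out$class_order <- classes
  for (nm in c("recall", "precision", "recall_raw", "precision_raw")) {
    out[[nm]] <- stats::setNames(as.numeric(obj[[nm]]), classes)
  }
  if (!is.null(obj$auc)) out$auc <- unlist(obj$auc)
  structure(out, class = "evaluation_report")
}
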