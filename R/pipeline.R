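#' End-to-end two-class SVM pipeline on synthetic data
#'
#' Simulates the cancer-like vs normal-like presets, runs the full
#' preprocessing chain, splits 60/10/30, reduces the training spectra to
#' `pca_k` principal components, Bayes-optimizes the SVM box constraint and
#' kernel scale by 5-fold cross-validated loss, trains the final model and
#' scores the held-out test set.
#'
#' @param seed Integer seed driving every random step.
#' @param n_per_class Spectra per class.
#' @param pca_k Principal components kept for the SVM.
#' @param n_iter Bayesian-optimization evaluations.
#' @param kernel SVM kernel.
#' @param contrast Class-contrast dial passed to [preset_profile()].
#' @return A list with `report` (an `evaluation_report` for the test set),
#'   `test_accuracy` (fraction), `cv_loss`, `best_config`, `trace`, `pca`,
#'   `svm`, `platt` and the three splits.
#' @export
run_two_class_svm <- function(seed = 1L, n_per_class = 135L, pca_k = 2L,
                              n_iter = 24L, kernel = "linear",
                              contrast = 1) {
  profiles <- list(preset_profile("cancer-like", contrast = contrast),
                   preset_profile("normal-like", contrast = contrast))
  raw <- simulate_dataset(profiles, n_per_class, seed = seed)
  clean <- preprocess(raw)
  parts <- split_dataset(clean, c(0.6, 0.1, 0.3),
                         seed = (as.numeric(seed) * 13 + 7) %% 2147483647)
  pca <- fit_pca(parts$train$matrix, k = pca_k)
  tr_scores <- pca$scores
  opt <- bayes_optimize(tr_scores, parts$train$labels, n_iter = n_iter,
                        seed = (as.numeric(seed) * 17 + 3) %% 2147483647,
                        kernel = kernel)
  svm <- train_svm(tr_scores, parts$train$labels, opt$best_config)
  calib <- platt_calibrate(svm)
  te_scores <- pca_transform(pca, parts$test$matrix)
  pred <- svm_predict(svm, te_scores)
  prob_pos <- platt_predict(calib, pred$scores)
  score_matrix <- cbind(prob_pos, 1 - prob_pos)
  colnames(score_matrix) <- svm$class_names
  report <- evaluation_report(parts$test$labels, pred$classes,
                              class_order = svm$class_names,
                              score_matrix = score_matrix,
                              cv_loss = opt$best_objective)
  list(report = report, test_accuracy = report$accuracy_raw,
       cv_loss = opt$best_objective, best_config = opt$best_config,
       trace = opt$trace, pca = pca, svm = svm, platt = calib,
       train = parts$train, val = parts$val, test = parts$test)
}

#' End-to-end five-class CNN pipeline on synthetic data
#'
#' Simulates the five built-in class presets, preprocesses, splits
#' 60/10/30, trains the 1-D CNN and evaluates the held-out test set.
#'
#' @param seed Integer seed.
#' @param n_per_class Spectra per class.
#' @param config A [train_config()]; epochs/learning rate live here.
#' @param arch Optional [cnn_architecture()].
#' @return A list with `report`, `test_accuracy` (fraction), `model`,
#'   `curves` and the three splits.
#' @export
run_five_class_cnn <- function(seed = 1L, n_per_class = 135L,
                               config = NULL, arch = NULL) {
  profiles <- lapply(preset_names(), preset_profile)
  raw <- simulate_dataset(profiles, n_per_class, seed = seed)
  clean <- preprocess(raw)
  parts <- split_dataset(clean, c(0.6, 0.1, 0.3),
                         seed = (as.numeric(seed) * 13 + 7) %% 2147483647)
  if (is.null(config)) {
    config <- train_config(seed = (as.numeric(seed) * 19 + 11) %% 2147483647)
  }
  fit <- train_cnn(parts$train, parts$val, arch = arch, config = config)
  pred <- cnn_predict(fit$model, parts$test)
  report <- evaluation_report(parts$test$labels, pred$classes,
                              class_order = fit$model$class_names,
                              score_matrix = pred$probabilities)
  list(report = report, test_accuracy = report$accuracy_raw,
       model = fit$model, curves = fit$curves,
       train = parts$train, val = parts$val, test = parts$test)
}
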