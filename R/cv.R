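# Cross-validation helpers shared by the decoders.

# Variance-scaled RBF width heuristic: 1 / (n_features * mean feature
# variance), so kernels are sensibly scaled for both sensor-space
# z-scores and vertex-space currents.
gamma_scale <- function(x) {
  v <- mean(apply(x, 2, stats::var))
  1 / (ncol(x) * max(v, 1e-12))
}

# Stratified fold assignment: permutes trials within each class and
# deals them round-robin into folds. Reduces the fold count (with a
# warning) when the smallest class has fewer trials than folds.
stratified_folds <- function(labels, folds) {
  n_min <- min(table(labels))
  if (n_min < folds) {
    warning(sprintf(
      "smallest class has %d trials; reducing folds from %d to %d",
      n_min, folds, n_min))
    folds <- n_min
  }
  assignment <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  list(assignment = assignment, folds = folds)
}

# Mean accuracy of repeated k-fold CV of an RBF-SVM on x (n x d) with
# labels y, using libsvm's internal (stratified) cross-validation, which
# draws its shuffles from R's RNG so results are reproducible under
# set.seed(). Returns accuracy in [0, 1].
repeated_cv_accuracy <- function(x, y, folds, repeats, cost, gamma) {
  folds <- min(folds, min(table(y)))
  acc <- vapply(seq_len(repeats), function(r) {
    e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
               scale = FALSE, cross = folds)$tot.accuracy
  }, numeric(1))
  mean(acc) / 100
}

# Per-trial CV predictions (R-level stratified folds) of an RBF-SVM.
cv_predictions <- function(x, y, folds, cost, gamma) {
  fs <- suppressWarnings(stratified_folds(y, folds))
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (k in seq_len(fs$folds)) {
    test <- fs$assignment == k
    m <- e1071::svm(x[!test, , drop = FALSE], y[!test], kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
    pred[test] <- predict(m, x[test, , drop = FALSE])
  }
  pred
}
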