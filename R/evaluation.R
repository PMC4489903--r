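#' Nested cross-validated classification accuracy
#'
#' Unbiased estimate of movement-type classification accuracy: outer
#' stratified folds hold out test trials; within each outer training
#' set, repeated stratified cross-validation selects the feature lag
#' (500-ms window, default slid in 100-ms steps over -500..500 ms) and
#' the SVM hyperparameters jointly by highest mean inner accuracy; the
#' outer test trials are then scored once by a decoder trained on the
#' whole outer training set with the selected settings. Selections never
#' see the outer test trials. Ties in inner accuracy are broken toward
#' the lag closest to the execution cue (where movement information is
#' expected to be strongest), then the earlier lag, then the more
#' regularized hyperparameters.
#'
#' @param features an `smf_set` or `escp_set` (or hemisphere slice).
#' @param outer_folds outer folds (default 10).
#' @param inner_folds,inner_repeats inner CV structure (default 10 x 10).
#' @param lag_window ms range of candidate lags (default `c(-500, 500)`).
#' @param cost_grid absolute cost candidates.
#' @param gamma_grid absolute gamma candidates, or `NULL` to use
#'   [default_gamma_factors()] times the variance-scaled heuristic
#'   computed on each outer training set.
#' @param seed RNG seed or `NULL`.
#' @return A `nested_cv_report`: list with `pooled_accuracy` (fraction
#'   correct over all outer test trials), `per_fold` (data.frame of
#'   fold accuracy and selections), `n_trials`, `n_correct`, `seed`.
#' @export
nested_cv_accuracy <- function(features, outer_folds = 10, inner_folds = 10,
                               inner_repeats = 10,
                               lag_window = c(-500, 500),
                               cost_grid = default_cost_grid(),
                               gamma_grid = NULL,
                               seed = NULL) {
  check_two_classes(features$labels)
  labels <- features$labels
  n <- length(labels)
  if (n < 2 * outer_folds)
    stop(sprintf("nested CV needs at least %d trials (2 per outer fold), got %d",
                 2 * outer_folds, n))
  lags <- features$lags[features$lags >= lag_window[1] &
                          features$lags <= lag_window[2]]
  if (length(lags) == 0) stop("`lag_window` contains no lags of the grid")
  with_seed_if(seed, {
    fs <- stratified_folds(labels, outer_folds)
    per_fold <- vector("list", fs$folds)
    correct <- logical(n)
    for (k in seq_len(fs$folds)) {
      test <- fs$assignment == k
      tr_labels <- labels[!test]
      gg <- gamma_grid %||% (default_gamma_factors() *
        gamma_scale(smf_stack(subset_trials(features, !test), lags)$x))
      grid <- expand.grid(gamma = sort(gg), cost = sort(cost_grid))
      best <- list(acc = -1, lag = Inf)
      for (l in lags) {
        x <- smf_at_lag(features, l)[!test, , drop = FALSE]
        for (g in seq_len(nrow(grid))) {
          a <- repeated_cv_accuracy(x, tr_labels, inner_folds,
                                    inner_repeats, grid$cost[g],
                                    grid$gamma[g])
          if (a > best$acc ||
                (a == best$acc && abs(l) < abs(best$lag)))
            best <- list(acc = a, lag = l, cost = grid$cost[g],
                         gamma = grid$gamma[g])
        }
      }
      x_all <- smf_at_lag(features, best$lag)
      model <- e1071::svm(x_all[!test, , drop = FALSE], tr_labels,
                          kernel = "radial", cost = best$cost,
                          gamma = best$gamma, scale = FALSE)
      pred <- predict(model, x_all[test, , drop = FALSE])
      correct[test] <- pred == labels[test]
      per_fold[[k]] <- data.frame(
        fold = k, n_test = sum(test),
        accuracy = mean(pred == labels[test]),
        lag = best$lag, cost = best$cost, gamma = best$gamma,
        inner_accuracy = best$acc)
    }
    structure(
      list(pooled_accuracy = mean(correct), n_correct = sum(correct),
           n_trials = n, per_fold = do.call(rbind, per_fold),
           fold_assignment = fs$assignment,
           outer_folds = fs$folds, seed = seed),
      class = "nested_cv_report"
    )
  })
}

#' @export
print.nested_cv_report <- function(x, ...) {
  cat(sprintf(
    "<nested_cv_report> pooled accuracy %.1f%% (%d/%d trials, %d outer folds)\n",
    100 * x$pooled_accuracy, x$n_correct, x$n_trials, x$outer_folds))
  invisible(x)
}

#' Cross-validated evaluation of onset detection
#'
#' For each fold of a stratified cross-validation, the full onset
#' decoder (class decoder, MI course, time triple, MI estimator,
#' duration/threshold optimization) is trained on the training trials,
#' with thresholds estimated only from training data. On each held-out
#' trial, lags are swept from -2000 ms in `sweep_step` intervals and the
#' first lag where the onset decoder fires is recorded (or the trial is
#' marked not-detected). Times are reported relative to the fold's
#' class-decoder training lag `t_star`. Selectivity compares detections
#' in the onset range (-500..500 ms) against the no-onset range
#' (-2000..-500 ms) with a one-sided Fisher's exact test.
#'
#' @param smf an `smf_set`.
#' @param folds CV folds (default 10).
#' @param sweep_step detection sweep interval in ms (default 200).
#' @param onset_range,no_onset_range ms ranges relative to `t_star`.
#' @param seed RNG seed or `NULL`.
#' @param ... passed to [optimize_onset_params()] (e.g. smaller grids).
#' @return An `onset_eval_report`: list with `first_detection`
#'   (per-trial ms relative to t_star, `NA` when not detected),
#'   `detection_rate` (histogram over relative lags plus an `"ND"`
#'   entry), counts in the two ranges, `sensitivity`, `specificity`,
#'   `fisher_p`, `degenerate` flag and per-fold selections.
#' @export
evaluate_onset_cv <- function(smf, folds = 10, sweep_step = 200,
                              onset_range = c(-500, 500),
                              no_onset_range = c(-2000, -500),
                              seed = NULL, ...) {
  check_two_classes(smf$labels)
  n <- length(smf$labels)
  if (n < folds) stop("need at least as many trials as folds")
  with_seed_if(seed, {
    fs <- stratified_folds(smf$labels, folds)
    first_rel <- rep(NA_real_, n)
    fold_info <- vector("list", fs$folds)
    degenerate <- FALSE
    for (k in seq_len(fs$folds)) {
      test <- fs$assignment == k
      train_set <- subset_trials(smf, !test)
      cls <- train_class_decoder(train_set)
      onset <- withCallingHandlers(
        train_onset_decoder(train_set, cls, ...),
        warning = function(w) {
          if (grepl("conservative candidate", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      if (onset$degenerate) degenerate <- TRUE
      sweep_lags <- smf$lags[(smf$lags - min(smf$lags)) %% sweep_step == 0]
      test_idx <- which(test)
      test_set <- subset_trials(smf, test)
      st <- smf_stack(test_set, sweep_lags)
      d <- detect(onset, st$x)
      D <- matrix(d$onset, length(test_idx), length(sweep_lags))
      hit <- rowSums(D) > 0
      first <- max.col(D, ties.method = "first")
      first_rel[test_idx[hit]] <- sweep_lags[first[hit]] - cls$t_star
      fold_info[[k]] <- data.frame(
        fold = k, t_star = cls$t_star, d_off = onset$d_off,
        d_on = onset$d_on, theta_mi = onset$theta_mi,
        theta_conf = onset$theta_conf)
    }
    detected <- !is.na(first_rel)
    in_range <- function(r) detected & first_rel >= r[1] & first_rel <= r[2]
    in_onset <- in_range(onset_range)
    in_no_onset <- detected & first_rel >= no_onset_range[1] &
      first_rel < no_onset_range[2]
    tab <- matrix(c(sum(in_onset), n - sum(in_onset),
                    sum(in_no_onset), n - sum(in_no_onset)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(range = c("onset", "no_onset"),
                                  detection = c("detected", "undetected")))
    rate <- table(factor(first_rel,
                         levels = sort(unique(stats::na.omit(first_rel)))))
    rate <- c(rate / n, ND = sum(!detected) / n)
    structure(
      list(first_detection = first_rel, detection_rate = rate,
           n_onset_range = sum(in_onset), n_no_onset_range = sum(in_no_onset),
           n_not_detected = sum(!detected), n_trials = n,
           sensitivity = sum(in_onset) / n,
           specificity = 1 - sum(in_no_onset) / n,
           fisher_p = fisher_exact_one_sided(tab), table = tab,
           degenerate = degenerate,
           per_fold = do.call(rbind, fold_info), seed = seed),
      class = "onset_eval_report"
    )
  })
}

#' @export
print.onset_eval_report <- function(x, ...) {
  cat(sprintf(
    paste0("<onset_eval_report> %d/%d first detections in the onset range,",
           " %d not detected\n  sensitivity %.2f, specificity %.2f,",
           " one-sided Fisher p = %.3g%s\n"),
    x$n_onset_range, x$n_trials, x$n_not_detected, x$sensitivity,
    x$specificity, x$fisher_p,
    if (x$degenerate) " [degenerate folds]" else ""))
  invisible(x)
}

# restrict an smf_set / escp_set to a logical or integer trial index
subset_trials <- function(smf, idx) {
  out <- smf
  out$values <- smf$values[idx, , , drop = FALSE]
  out$labels <- factor(smf$labels[idx], levels = levels(smf$labels))
  out
}

#' One-sided binomial test against chance
#'
#' Exact upper-tail binomial probability of at least `n_correct`
#' successes out of `n_total` at the chance rate (or the two-sided
#' exact test when `one_sided = FALSE`).
#'
#' @param n_correct,n_total counts with `0 <= n_correct <= n_total`.
#' @param chance success probability under the null (default 0.5).
#' @param one_sided upper-tail test (default `TRUE`).
#' @return p-value.
#' @export
binomial_test_vs_chance <- function(n_correct, n_total, chance = 0.5,
                                    one_sided = TRUE) {
  if (n_total < 1 || n_correct < 0 || n_correct > n_total)
    stop("need 0 <= n_correct <= n_total with n_total >= 1")
  stats::binom.test(n_correct, n_total, p = chance,
                    alternative = if (one_sided) "greater" else
                      "two.sided")$p.value
}

#' One-sided Fisher's exact test on a 2x2 table
#'
#' Hypergeometric tail probability of the detection count in cell
#' (1, 1) being at least as large as observed, i.e. detection enriched
#' in the first row (the onset / different-state condition).
#'
#' @param table 2x2 matrix of non-negative counts; rows are the two
#'   conditions, column 1 the detections.
#' @return p-value. A table with a zero margin gives `p = 1` with a
#'   warning.
#' @export
fisher_exact_one_sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("`table` must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin in the contingency table; p = 1")
    return(1)
  }
  stats::fisher.test(table, alternative = "greater")$p.value
}

#' Paired two-tailed Student's t-test
#'
#' @param values_a,values_b paired per-subject values (equal length
#'   >= 2).
#' @return List with `t` and `p`.
#' @export
paired_t_two_tailed <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 2)
    stop("`values_a` and `values_b` must be paired with length >= 2")
  if (stats::sd(values_a - values_b) == 0)
    stop("differences have zero variance; t statistic undefined")
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}
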