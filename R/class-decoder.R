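#' Default hyperparameter grids for the RBF-SVM decoders
#'
#' Log-spaced candidates for the soft-margin cost, and multiplicative
#' factors applied to the variance-scaled kernel-width heuristic
#' `1 / (n_features * mean feature variance)` to form the gamma grid.
#' Both are deliberately coarse: with 40-trial sessions a fine grid is
#' mostly fit to inner-fold noise, and the grids are arguments
#' everywhere, so users with more data can widen them.
#'
#' @return Numeric vector of candidate values.
#' @export
default_cost_grid <- function() 2^c(-1, 5)

#' @rdname default_cost_grid
#' @export
default_gamma_factors <- function() 2^c(-2, 1)

#' Cross-validated accuracy at each lag
#'
#' Estimates movement-type classification accuracy of an RBF-SVM at each
#' lag of the feature set by repeated stratified k-fold
#' cross-validation. This is the accuracy course used to pick the class
#' decoder's training lag.
#'
#' @param smf an `smf_set` (or `escp_set`) with labels.
#' @param lag_window length-2 numeric, ms range of lags to scan
#'   (default `c(-500, 500)` around the execution cue).
#' @param cv_folds folds (default 10; reduced with a warning if a class
#'   has fewer trials).
#' @param cv_repeats repetitions of the CV (default 10).
#' @param cost,gamma SVM hyperparameters used for the scan; `gamma`
#'   defaults to the variance-scaled heuristic computed over the
#'   scanned lags.
#' @param seed RNG seed or `NULL`.
#' @return Named numeric vector: mean CV accuracy in `[0, 1]` per lag.
#' @export
scan_accuracy <- function(smf, lag_window = c(-500, 500), cv_folds = 10,
                          cv_repeats = 10, cost = 1,
                          gamma = NULL, seed = NULL) {
  check_two_classes(smf$labels)
  lags <- smf$lags[smf$lags >= lag_window[1] & smf$lags <= lag_window[2]]
  if (length(lags) == 0) stop("`lag_window` contains no lags of the grid")
  if (is.null(gamma)) gamma <- gamma_scale(smf_stack(smf, lags)$x)
  n_min <- min(table(smf$labels))
  if (n_min < cv_folds)
    warning(sprintf("smallest class has %d trials; using %d folds", n_min, n_min))
  with_seed_if(seed, {
    acc <- vapply(lags, function(l) {
      repeated_cv_accuracy(smf_at_lag(smf, l), smf$labels,
                           cv_folds, cv_repeats, cost, gamma)
    }, numeric(1))
    stats::setNames(acc, lags)
  })
}

#' Lag of peak classification accuracy
#'
#' @param accuracy_course named numeric vector as returned by
#'   [scan_accuracy()] (names are lags in ms).
#' @param lag_window ms range to search (default `c(-500, 500)`).
#' @return The lag (ms) with maximal accuracy; ties go to the earliest
#'   lag.
#' @export
select_peak_lag <- function(accuracy_course, lag_window = c(-500, 500)) {
  lags <- as.numeric(names(accuracy_course))
  keep <- lags >= lag_window[1] & lags <= lag_window[2]
  if (!any(keep)) stop("no lags inside `lag_window`")
  lags <- lags[keep]; acc <- accuracy_course[keep]
  ord <- order(lags)
  lags <- lags[ord]; acc <- acc[ord]
  lags[which.max(acc)]   # which.max returns the first (earliest) maximum
}

#' Train the movement-type class decoder
#'
#' Trains an RBF-kernel SVM on the SMF vectors at the training lag
#' `t_star` (the lag of peak cross-validated accuracy within +/-500 ms
#' of the execution cue, found with [scan_accuracy()] if not supplied).
#' Hyperparameters are chosen from the grids by repeated stratified
#' cross-validation on the training set; ties go to the smallest cost,
#' then the smallest kernel width (the most regularized candidate).
#'
#' @inheritParams scan_accuracy
#' @param t_star training lag in ms; `NULL` to select it from the data.
#' @param cost_grid absolute cost candidates.
#' @param gamma_grid absolute gamma candidates, or `NULL` to use
#'   [default_gamma_factors()] times the variance-scaled heuristic at
#'   `t_star`.
#' @return A `class_decoder` with the fitted model, `t_star`, selected
#'   `cost` and `gamma`, the accuracy course (when scanned) and the
#'   class levels.
#' @export
train_class_decoder <- function(smf, t_star = NULL,
                                cost_grid = default_cost_grid(),
                                gamma_grid = NULL,
                                lag_window = c(-500, 500), cv_folds = 10,
                                cv_repeats = 10, seed = NULL) {
  check_two_classes(smf$labels)
  with_seed_if(seed, {
    course <- NULL
    if (is.null(t_star)) {
      course <- scan_accuracy(smf, lag_window, cv_folds, cv_repeats)
      t_star <- select_peak_lag(course, lag_window)
    }
    x <- smf_at_lag(smf, t_star)
    if (is.null(gamma_grid))
      gamma_grid <- default_gamma_factors() * gamma_scale(x)
    grid <- expand.grid(gamma = sort(gamma_grid), cost = sort(cost_grid))
    cv <- vapply(seq_len(nrow(grid)), function(i) {
      repeated_cv_accuracy(x, smf$labels, cv_folds, cv_repeats,
                           grid$cost[i], grid$gamma[i])
    }, numeric(1))
    # expand.grid varies gamma fastest and the grids are sorted, so the
    # first maximum is the smallest (cost, gamma) pair
    best <- which.max(cv)
    model <- e1071::svm(x, smf$labels, kernel = "radial",
                        cost = grid$cost[best], gamma = grid$gamma[best],
                        scale = FALSE)
    structure(
      list(model = model, t_star = t_star, cost = grid$cost[best],
           gamma = grid$gamma[best], channels = smf$channels,
           levels = levels(smf$labels), accuracy_course = course,
           n_features = dim(smf$values)[2]),
      class = "class_decoder"
    )
  })
}

#' Predict movement type from an SMF vector
#'
#' @param object a `class_decoder`.
#' @param newdata numeric vector (one SMF sample) or matrix with one
#'   sample per row; the feature dimension must match training.
#' @param ... unused.
#' @return Factor of predicted movement types.
#' @exportS3Method stats::predict
predict.class_decoder <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_features)
    stop(sprintf("feature dimension %d does not match training dimension %d",
                 ncol(newdata), object$n_features))
  predict(object$model, newdata)
}

#' @export
print.class_decoder <- function(x, ...) {
  cat(sprintf(
    "<class_decoder> RBF-SVM (%s vs %s) at t* = %g ms, cost = %g, gamma = %g\n",
    x$levels[1], x$levels[2], x$t_star, x$cost, x$gamma))
  invisible(x)
}

check_two_classes <- function(labels) {
  tab <- table(labels)
  if (length(tab) != 2)
    stop(sprintf("exactly two movement types required, got %d", length(tab)))
  if (min(tab) < 2)
    stop("at least 2 trials per movement type required")
  invisible(TRUE)
}
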