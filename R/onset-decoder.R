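#' Plug-in mutual information of a confusion table
#'
#' Mutual information (bits) between actual and inferred movement type,
#' computed from a contingency table of counts by the plug-in estimator
#' `sum p(a,b) log2[p(a,b) / (p(a) p(b))]` with `0 log 0 = 0`. For two
#' balanced classes the value lies in `[0, 1]` bits.
#'
#' @param confusion matrix of non-negative counts (rows: actual,
#'   columns: inferred).
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) stop("counts must be non-negative")
  n <- sum(confusion)
  if (n <= 0) stop("total count must be positive")
  p <- confusion / n
  pr <- rowSums(p); pc <- colSums(p)
  e <- outer(pr, pc)
  nz <- p > 0
  max(0, sum(p[nz] * log2(p[nz] / e[nz])))
}

#' Mutual-information course over lags
#'
#' At each lag, the movement type of every trial is inferred by
#' stratified cross-validation of an RBF-SVM (each trial predicted by a
#' model that never saw it); the confusion of actual versus inferred
#' types gives the plug-in mutual information at that lag.
#'
#' @inheritParams scan_accuracy
#' @param cv_folds folds for the CV predictions (default 10).
#' @return An `mi_course`: named numeric vector, bits per lag, over the
#'   full lag grid of `smf`.
#' @export
compute_mi_course <- function(smf, cv_folds = 10, cost = 1,
                              gamma = NULL, seed = NULL) {
  check_two_classes(smf$labels)
  if (is.null(gamma)) gamma <- gamma_scale(smf_stack(smf, smf$lags)$x)
  with_seed_if(seed, {
    mi <- vapply(smf$lags, function(l) {
      pred <- cv_predictions(smf_at_lag(smf, l), smf$labels,
                             cv_folds, cost, gamma)
      mutual_information(table(smf$labels, pred))
    }, numeric(1))
    stats::setNames(mi, smf$lags)
  })
}

# --- Gaussian-process regression wrapper -------------------------------

# Median-heuristic RBF width for kernlab's rbfdot (sigma multiplies the
# squared distance); deterministic.
median_sigma <- function(x) {
  n <- nrow(x)
  idx <- if (n > 400) as.integer(seq(1, n, length.out = 400)) else seq_len(n)
  d2 <- as.numeric(stats::dist(x[idx, , drop = FALSE]))^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) 1 else 1 / m
}

# Squared-exponential GP regression on centred targets with fixed
# observation-noise variance; kernel width by the median heuristic
# unless supplied.
fit_gpr <- function(x, y, sigma = NULL, noise_var = 0.01) {
  if (any(!is.finite(y))) stop("regression targets must be finite")
  if (is.null(sigma)) sigma <- median_sigma(x)
  ybar <- mean(y)
  model <- if (stats::sd(y) == 0) NULL else
    kernlab::gausspr(x, y - ybar, kernel = "rbfdot",
                     kpar = list(sigma = sigma), var = noise_var,
                     scaled = FALSE)
  structure(list(model = model, ybar = ybar, sigma = sigma,
                 noise_var = noise_var, n_features = ncol(x)),
            class = "gpr_model")
}

#' @exportS3Method stats::predict
predict.gpr_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_features)
    stop(sprintf("feature dimension %d does not match training dimension %d",
                 ncol(newdata), object$n_features))
  if (is.null(object$model)) return(rep(object$ybar, nrow(newdata)))
  as.numeric(predict(object$model, newdata)) + object$ybar
}

# -----------------------------------------------------------------------

#' Select the three MI-estimator training lags
#'
#' The MI estimator is trained on SMF vectors at three lags: the class
#' decoder's training lag `t_star` and one lag before and one after it.
#' Every candidate (t_pre, t_post) pair is scored by fitting the
#' estimator on the triple (each trial contributes one sample per
#' triple lag, with the lag's population MI as target), predicting MI
#' for every trial at every lag of the grid, averaging predictions per
#' lag, and correlating that predicted course with the observed MI
#' course. The pair with the largest Pearson correlation wins; ties go
#' to the pair closest to `t_star` (smallest `|t_pre - t_star| +
#' |t_post - t_star|`, then earlier `t_pre`).
#'
#' @param smf an `smf_set`.
#' @param mi_course named vector from [compute_mi_course()].
#' @param t_star class-decoder training lag (ms).
#' @param pre_offsets,post_offsets candidate offsets (ms) of t_pre and
#'   t_post relative to `t_star`; defaults are multiples of 100 ms up to
#'   1 s on either side, clipped to the lag grid.
#' @param noise_var GP observation-noise variance.
#' @return List with `triple` (t_pre, t_star, t_post), `correlation`,
#'   and the full `search` table.
#' @export
select_time_triple <- function(smf, mi_course, t_star,
                               pre_offsets = seq(-1000, -100, by = 100),
                               post_offsets = seq(100, 1000, by = 100),
                               noise_var = 0.01) {
  lags <- smf$lags
  pre_cand <- intersect(t_star + pre_offsets, lags)
  post_cand <- intersect(t_star + post_offsets, lags)
  if (length(pre_cand) == 0 || length(post_cand) == 0)
    stop("no candidate (t_pre, t_post) pairs on the lag grid")
  all_x <- smf_stack(smf, lags)
  n_tr <- dim(smf$values)[1]
  grid <- expand.grid(t_pre = pre_cand, t_post = post_cand)
  grid$correlation <- NA_real_
  for (i in seq_len(nrow(grid))) {
    triple <- c(grid$t_pre[i], t_star, grid$t_post[i])
    st <- smf_stack(smf, triple)
    fit <- fit_gpr(st$x, mi_course[as.character(st$lag)],
                   noise_var = noise_var)
    pred <- predict(fit, all_x$x)
    per_lag <- tapply(pred, all_x$lag, mean)
    per_lag <- per_lag[as.character(lags)]
    grid$correlation[i] <-
      suppressWarnings(stats::cor(per_lag, as.numeric(mi_course)))
  }
  grid$correlation[!is.finite(grid$correlation)] <- -Inf
  ord <- order(-grid$correlation,
               abs(grid$t_pre - t_star) + abs(grid$t_post - t_star),
               grid$t_pre, grid$t_post)
  best <- grid[ord[1], ]
  list(triple = c(t_pre = best$t_pre, t_star = t_star, t_post = best$t_post),
       correlation = best$correlation, search = grid)
}

#' Train the mutual-information estimator
#'
#' Gaussian-process regression from a single SMF vector to the expected
#' mutual information between actual and inferred movement type.
#' Training samples are the SMF vectors of every trial at the three
#' triple lags; the target of each sample is the population MI of its
#' lag (all trials at a lag share the target), which keeps the estimator
#' a function of one SMF vector as required online.
#'
#' @inheritParams select_time_triple
#' @param triple numeric (t_pre, t_star, t_post) lags in ms.
#' @return A `gpr_model`; `predict()` returns estimated MI in bits.
#' @export
train_mi_estimator <- function(smf, triple, mi_course, noise_var = 0.01) {
  st <- smf_stack(smf, triple)
  fit_gpr(st$x, mi_course[as.character(st$lag)], noise_var = noise_var)
}

#' Train the R_on / R_off movement detector
#'
#' An RBF-SVM trained to separate SMF samples from the pre-movement
#' period R_off (starting at -2000 ms, duration `d_off`) from samples in
#' the movement period R_on (starting at `t_star`, duration `d_on`).
#' Its signed decision value is the movement confidence, oriented so
#' that larger values mean "more like R_on".
#'
#' @param smf an `smf_set`.
#' @param t_star class-decoder training lag (ms), start of R_on.
#' @param d_off,d_on period durations in ms (> 0).
#' @param cost,gamma SVM hyperparameters; `gamma` defaults to the
#'   variance-scaled heuristic over the period samples.
#' @return A `movement_detector`.
#' @export
train_movement_detector <- function(smf, t_star, d_off, d_on, cost = 1,
                                    gamma = NULL) {
  if (d_off <= 0 || d_on <= 0) stop("period durations must be positive")
  off_lags <- smf$lags[smf$lags >= -2000 & smf$lags <= -2000 + d_off]
  on_lags <- smf$lags[smf$lags >= t_star & smf$lags <= t_star + d_on]
  if (length(off_lags) == 0 || length(on_lags) == 0)
    stop("R_off or R_on contains no lags of the grid")
  if (max(off_lags) >= min(on_lags))
    stop(sprintf("R_off (ends %g ms) overlaps R_on (starts %g ms)",
                 max(off_lags), min(on_lags)))
  x <- rbind(smf_stack(smf, off_lags)$x, smf_stack(smf, on_lags)$x)
  if (is.null(gamma)) gamma <- gamma_scale(x)
  n_tr <- dim(smf$values)[1]
  y <- factor(rep(c("off", "on"),
                  c(length(off_lags) * n_tr, length(on_lags) * n_tr)),
              levels = c("off", "on"))
  model <- e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE, decision.values = TRUE)
  dv <- attr(predict(model, x, decision.values = TRUE), "decision.values")
  flip <- if (mean(dv[y == "on"]) >= mean(dv[y == "off"])) 1 else -1
  structure(
    list(model = model, flip = flip, d_off = d_off, d_on = d_on,
         t_star = t_star, off_lags = off_lags, on_lags = on_lags,
         n_features = dim(smf$values)[2]),
    class = "movement_detector"
  )
}

#' Movement confidence of SMF samples
#'
#' @param detector a `movement_detector`.
#' @param x SMF vector or matrix (samples in rows).
#' @return Numeric confidence values (signed decision function,
#'   increasing toward R_on).
#' @export
detector_confidence <- function(detector, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != detector$n_features)
    stop(sprintf("feature dimension %d does not match training dimension %d",
                 ncol(x), detector$n_features))
  dv <- attr(predict(detector$model, x, decision.values = TRUE),
             "decision.values")
  as.numeric(dv) * detector$flip
}

#' Optimize onset-decoder durations and thresholds
#'
#' Exhaustive grid search over the R_off/R_on durations and the two
#' detection thresholds. For each duration pair a movement detector is
#' trained; threshold candidates are quantiles of the training-set MI
#' estimates and confidences. The objective of a parameter set is the
#' number of training trials whose first detection (sweeping lags from
#' -2000 ms at `sweep_step` intervals) falls within +/-500 ms of
#' `t_star` and whose movement type is classified correctly at that
#' lag. Ties prefer larger thresholds (more conservative), then smaller
#' durations. If no parameter set detects anything, the most
#' conservative candidate is returned with `degenerate = TRUE` and a
#' warning.
#'
#' @param smf an `smf_set`.
#' @param class_decoder a trained [train_class_decoder()] decoder.
#' @param mi_estimator a `gpr_model` from [train_mi_estimator()].
#' @param time_triple the (t_pre, t_star, t_post) lags used to train
#'   the estimator (stored on the returned decoder).
#' @param d_off_grid,d_on_grid duration candidates in ms; the default
#'   resolution matches the 200-ms online decision cadence.
#' @param theta_probs quantile probabilities defining both threshold
#'   grids (data-driven, scale-free).
#' @param theta_mi_fixed,theta_conf_fixed optional fixed thresholds
#'   overriding the corresponding threshold grid (the online analogue
#'   of thresholds set by hand before a closed-loop session).
#' @param detector_cost,detector_gamma detector SVM hyperparameters.
#' @param sweep_step detection sweep interval in ms (default 200,
#'   the online update period).
#' @param tol_ms detection tolerance around `t_star` (default 500).
#' @return An `onset_decoder`.
#' @export
optimize_onset_params <- function(smf, class_decoder, mi_estimator,
                                  time_triple = NULL,
                                  d_off_grid = seq(200, 1000, by = 200),
                                  d_on_grid = seq(200, 1000, by = 200),
                                  theta_probs = seq(0.1, 0.9, by = 0.1),
                                  theta_mi_fixed = NULL,
                                  theta_conf_fixed = NULL,
                                  detector_cost = 1,
                                  detector_gamma = NULL,
                                  sweep_step = 200, tol_ms = 500) {
  t_star <- class_decoder$t_star
  sweep_lags <- smf$lags[(smf$lags - min(smf$lags)) %% sweep_step == 0]
  st <- smf_stack(smf, sweep_lags)
  n_tr <- dim(smf$values)[1]
  n_lag <- length(sweep_lags)
  mi_mat <- matrix(predict(mi_estimator, st$x), n_tr, n_lag)
  cls_ok <- matrix(predict(class_decoder, st$x) ==
                     rep(smf$labels, times = n_lag), n_tr, n_lag)
  mi_probs <- conf_probs <- theta_probs
  if (!is.null(theta_mi_fixed)) mi_probs <- 1
  if (!is.null(theta_conf_fixed)) conf_probs <- 1
  mi_thr <- if (is.null(theta_mi_fixed))
    stats::quantile(mi_mat, mi_probs, names = FALSE) else theta_mi_fixed
  d_grid <- expand.grid(d_off = d_off_grid, d_on = d_on_grid)
  valid <- vapply(seq_len(nrow(d_grid)), function(i) {
    off_end <- max(smf$lags[smf$lags <= -2000 + d_grid$d_off[i]])
    on_start <- t_star
    off_end < on_start && t_star + 100 <= max(smf$lags)
  }, logical(1))
  d_grid <- d_grid[valid, , drop = FALSE]
  if (nrow(d_grid) == 0) stop("no valid (d_off, d_on) candidates")

  rows <- vector("list", nrow(d_grid))
  detectors <- vector("list", nrow(d_grid))
  for (i in seq_len(nrow(d_grid))) {
    det <- train_movement_detector(smf, t_star, d_grid$d_off[i],
                                   d_grid$d_on[i], detector_cost,
                                   detector_gamma)
    detectors[[i]] <- det
    conf_mat <- matrix(detector_confidence(det, st$x), n_tr, n_lag)
    conf_thr <- if (is.null(theta_conf_fixed))
      stats::quantile(conf_mat, conf_probs, names = FALSE) else theta_conf_fixed
    res <- expand.grid(p_mi = mi_probs, p_conf = conf_probs)
    res$theta_mi <- mi_thr[match(res$p_mi, mi_probs)]
    res$theta_conf <- conf_thr[match(res$p_conf, conf_probs)]
    res$objective <- vapply(seq_len(nrow(res)), function(k) {
      D <- mi_mat >= res$theta_mi[k] & conf_mat >= res$theta_conf[k]
      hit <- rowSums(D) > 0
      first <- max.col(D, ties.method = "first")
      ok <- hit & abs(sweep_lags[first] - t_star) <= tol_ms &
        cls_ok[cbind(seq_len(n_tr), first)]
      sum(ok)
    }, numeric(1))
    res$d_off <- d_grid$d_off[i]; res$d_on <- d_grid$d_on[i]
    res$det_index <- i
    rows[[i]] <- res
  }
  search <- do.call(rbind, rows)
  ord <- order(-search$objective, -search$p_mi, -search$p_conf,
               search$d_off, search$d_on)
  best <- search[ord[1], ]
  degenerate <- best$objective == 0
  if (degenerate)
    warning("no parameter set produced a correct detection; ",
            "returning the most conservative candidate")
  structure(
    list(mi_estimator = mi_estimator,
         detector = detectors[[best$det_index]],
         time_triple = time_triple, t_star = t_star,
         d_off = best$d_off, d_on = best$d_on,
         theta_mi = best$theta_mi, theta_conf = best$theta_conf,
         sweep_step = sweep_step, objective = best$objective,
         n_trials = n_tr, degenerate = degenerate,
         search = search[order(search$det_index, search$p_mi, search$p_conf),
                         c("d_off", "d_on", "p_mi", "p_conf",
                           "theta_mi", "theta_conf", "objective")]),
    class = "onset_decoder"
  )
}

#' Train the full onset decoder
#'
#' Convenience wrapper chaining [compute_mi_course()],
#' [select_time_triple()], [train_mi_estimator()] and
#' [optimize_onset_params()].
#'
#' @inheritParams optimize_onset_params
#' @param seed RNG seed (used for the CV inside the MI course).
#' @param ... passed to [optimize_onset_params()].
#' @return An `onset_decoder`.
#' @export
train_onset_decoder <- function(smf, class_decoder, seed = NULL, ...) {
  with_seed_if(seed, {
    mi_course <- compute_mi_course(smf)
    tt <- select_time_triple(smf, mi_course, class_decoder$t_star)
    est <- train_mi_estimator(smf, tt$triple, mi_course)
    optimize_onset_params(smf, class_decoder, est,
                          time_triple = tt$triple, ...)
  })
}

#' Evaluate the onset decoder on one SMF vector
#'
#' Movement onset is declared when the estimated mutual information and
#' the movement confidence both reach their thresholds (inclusive
#' comparison at both).
#'
#' @param decoder an `onset_decoder`.
#' @param smf_vector numeric SMF vector, or matrix of vectors in rows.
#' @return List with `onset` (logical), `mi_est` and `confidence`
#'   (numeric), one element per input row.
#' @export
detect <- function(decoder, smf_vector) {
  stopifnot(inherits(decoder, "onset_decoder"))
  mi <- predict(decoder$mi_estimator, smf_vector)
  conf <- detector_confidence(decoder$detector, smf_vector)
  list(onset = mi >= decoder$theta_mi & conf >= decoder$theta_conf,
       mi_est = mi, confidence = conf)
}

#' @export
print.onset_decoder <- function(x, ...) {
  cat(sprintf(
    paste0("<onset_decoder> t* = %g ms, triple = (%s) ms\n",
           "  R_off 2000..%g ms pre, d_off = %g ms; R_on from t*, d_on = %g ms\n",
           "  theta_mi = %.4g bits, theta_conf = %.4g; objective %d/%d trials%s\n"),
    x$t_star,
    if (is.null(x$time_triple)) "?" else paste(x$time_triple, collapse = ", "),
    -2000 + x$d_off, x$d_off, x$d_on, x$theta_mi, x$theta_conf,
    x$objective, x$n_trials, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
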