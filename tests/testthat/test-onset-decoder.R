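# independent entropy-based oracle for the plug-in MI
mi_oracle <- function(tab) {
  n <- sum(tab)
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  H(rowSums(tab) / n) + H(colSums(tab) / n) - H(as.numeric(tab) / n)
}

test_that("plug-in mutual information matches its definition and oracle", {
  expect_equal(mutual_information(matrix(c(20, 0, 0, 20), 2)), 1)
  expect_equal(mutual_information(matrix(c(10, 10, 10, 10), 2)), 0)
  tab <- matrix(c(15, 5, 5, 15), 2)
  expect_equal(mutual_information(tab), mi_oracle(tab), tolerance = 1e-12)
  expect_error(mutual_information(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(mutual_information(matrix(0, 2, 2)), "positive")
  set.seed(21)
  for (i in 1:25) {
    t2 <- matrix(rpois(4, 8), 2)
    if (sum(t2) == 0) next
    mi <- mutual_information(t2)
    expect_gte(mi, 0)
    expect_lte(mi, 1 + 1e-12)
    expect_equal(mi, mutual_information(t2[2:1, 2:1]))
    expect_equal(mi, mi_oracle(t2), tolerance = 1e-10)
  }
})

test_that("the MI course is high at informative lags and near zero on noise", {
  sep <- separable_smf(peak = 0, margin = 8, noise = 0.05, seed = 22)
  course <- compute_mi_course(sep, seed = 23)
  expect_length(course, length(sep$lags))
  expect_equal(unname(course[["0"]]), 1)
  nul <- null_smf(n_per = 12, d = 6, lags = seq(-400, 400, 200), seed = 24)
  nc <- compute_mi_course(nul, seed = 25)
  expect_lt(max(nc), 0.3)
  expect_lt(mean(nc), 0.12)
})

test_that("the GP regressor reproduces constants and recovers a linear map", {
  set.seed(26)
  x <- matrix(rnorm(150 * 2), 150, 2)
  const <- smfbmi:::fit_gpr(x[1:40, ], rep(0.5, 40))
  expect_equal(predict(const, x[41:60, ]), rep(0.5, 20), tolerance = 1e-3)
  y <- 2 * x[, 1]
  fit <- smfbmi:::fit_gpr(x[1:100, ], y[1:100], noise_var = 2e-3)
  rmse <- sqrt(mean((predict(fit, x[101:150, ]) - y[101:150])^2))
  expect_lt(rmse, 0.05 * diff(range(y)))
  expect_identical(predict(fit, x[101:110, ]), predict(fit, x[101:110, ]))
  expect_error(smfbmi:::fit_gpr(x, c(rep(1, 149), NA)), "finite")
})

test_that("time-triple selection maximizes the predicted/observed MI correlation", {
  s <- hi_session()
  course <- hi_course()
  single <- select_time_triple(s$smf, course, 0, pre_offsets = -200,
                               post_offsets = 300)
  expect_equal(unname(single$triple), c(-200, 0, 300))
  tt <- select_time_triple(s$smf, course, 0,
                           pre_offsets = seq(-400, -100, 100),
                           post_offsets = seq(100, 400, 100))
  expect_true(tt$triple["t_pre"] < 0 && tt$triple["t_post"] > 0)
  expect_equal(tt$correlation, max(tt$search$correlation))
  # exhaustive check: every candidate re-scored in isolation agrees
  for (i in seq_len(nrow(tt$search))) {
    alone <- select_time_triple(s$smf, course, 0,
                                pre_offsets = tt$search$t_pre[i],
                                post_offsets = tt$search$t_post[i])
    expect_equal(alone$correlation, tt$search$correlation[i],
                 tolerance = 1e-10)
  }
  expect_error(select_time_triple(s$smf, course, 0, pre_offsets = -5000,
                                  post_offsets = 5000), "no candidate")
})

test_that("the movement detector separates R_on from R_off when movement exists", {
  s <- hi_session()
  det <- train_movement_detector(s$smf, 0, d_off = 600, d_on = 400)
  on_conf <- detector_confidence(det, smfbmi:::smf_stack(s$smf, det$on_lags)$x)
  off_conf <- detector_confidence(det, smfbmi:::smf_stack(s$smf, det$off_lags)$x)
  expect_gt(mean(on_conf), mean(off_conf))
  expect_error(train_movement_detector(s$smf, -1500, 1000, 400), "overlaps")
})

test_that("on rest-only data held-out confidences do not distinguish the periods", {
  nul <- null_smf(n_per = 12, d = 8, lags = seq(-2000, 1000, 200), seed = 29)
  train <- smfbmi:::subset_trials(nul, 1:12)
  heldout <- smfbmi:::subset_trials(nul, 13:24)
  det <- train_movement_detector(train, 0, d_off = 600, d_on = 600)
  con <- detector_confidence(det, smfbmi:::smf_stack(heldout, det$on_lags)$x)
  coff <- detector_confidence(det, smfbmi:::smf_stack(heldout, det$off_lags)$x)
  obs <- mean(con) - mean(coff)
  pooled <- c(con, coff)
  set.seed(30)
  null_diff <- replicate(500, {
    p <- sample(pooled)
    mean(p[seq_along(con)]) - mean(p[-seq_along(con)])
  })
  p_perm <- mean(abs(null_diff) >= abs(obs))
  expect_gt(p_perm, 0.05)
})

test_that("a monotone feature ramp yields monotone detector confidence", {
  lags <- seq(-2000, 1000, 200)
  ramp <- seq(0, 4, length.out = length(lags))
  vals <- array(0, c(10, 2, length(lags)))
  set.seed(31)
  for (j in seq_along(lags))
    vals[, , j] <- matrix(rnorm(20, mean = ramp[j], sd = 0.05), 10, 2)
  smf <- make_smf_set(vals, lags, rep_len(c("grasp", "open"), 10))
  det <- train_movement_detector(smf, 0, d_off = 600, d_on = 600)
  # monotone within the span covered by training samples (an RBF
  # decision function decays back toward zero far outside it)
  span <- lags[lags <= max(det$on_lags)]
  conf_by_lag <- vapply(span, function(l)
    mean(detector_confidence(det, smfbmi:::smf_at_lag(smf, l))), numeric(1))
  expect_gt(cor(conf_by_lag, span, method = "spearman"), 0.9)
  # every R_on lag scores above every R_off lag
  expect_gt(min(conf_by_lag[span >= 0]), max(conf_by_lag[span <= -1400]))
})

test_that("the onset parameter search matches a brute-force objective oracle", {
  s <- hi_session()
  cls <- hi_cls()
  course <- hi_course()
  est <- train_mi_estimator(s$smf, c(-300, cls$t_star, 300), course)
  dec <- optimize_onset_params(s$smf, cls, est,
                               d_off_grid = c(400, 600), d_on_grid = c(200, 400),
                               theta_probs = c(0.3, 0.7))
  # brute force: recompute the objective for every searched combination
  sweep_lags <- s$smf$lags[(s$smf$lags + 2000) %% 200 == 0]
  n <- length(s$smf$labels)
  for (r in seq_len(nrow(dec$search))) {
    row <- dec$search[r, ]
    det <- train_movement_detector(s$smf, cls$t_star, row$d_off, row$d_on)
    obj <- 0
    for (i in seq_len(n)) {
      first <- NA
      for (l in sweep_lags) {
        v <- s$smf$values[i, , match(l, s$smf$lags)]
        mi <- predict(est, v)
        conf <- detector_confidence(det, v)
        if (mi >= row$theta_mi && conf >= row$theta_conf) { first <- l; break }
      }
      if (!is.na(first) && abs(first - cls$t_star) <= 500 &&
            predict(cls, s$smf$values[i, , match(first, s$smf$lags)]) ==
              s$smf$labels[i])
        obj <- obj + 1
    }
    expect_equal(row$objective, obj)
  }
  expect_equal(dec$objective, max(dec$search$objective))
  # single grid point is returned as-is
  one <- optimize_onset_params(s$smf, cls, est, d_off_grid = 600,
                               d_on_grid = 400, theta_probs = 0.5)
  expect_equal(c(one$d_off, one$d_on), c(600, 400))
})

test_that("detection combines the two thresholds with inclusive comparisons", {
  s <- hi_session()
  cls <- hi_cls()
  course <- hi_course()
  est <- train_mi_estimator(s$smf, c(-300, cls$t_star, 300), course)
  dec <- optimize_onset_params(s$smf, cls, est, d_off_grid = 600,
                               d_on_grid = 400, theta_probs = 0.5)
  v <- s$smf$values[1, , match(cls$t_star, s$smf$lags)]
  never <- dec; never$theta_mi <- Inf; never$theta_conf <- Inf
  expect_false(detect(never, v)$onset)
  always <- dec; always$theta_mi <- -Inf; always$theta_conf <- -Inf
  expect_true(detect(always, v)$onset)
  d <- detect(dec, v)
  exact <- dec; exact$theta_mi <- d$mi_est; exact$theta_conf <- d$confidence
  expect_true(detect(exact, v)$onset)
  expect_error(detect(dec, v[-1]), "dimension")
})

test_that("raising either threshold never increases the number of detections", {
  s <- hi_session()
  cls <- hi_cls()
  est <- train_mi_estimator(s$smf, c(-300, cls$t_star, 300),
                            hi_course())
  dec <- optimize_onset_params(s$smf, cls, est, d_off_grid = 600,
                               d_on_grid = 400, theta_probs = 0.5)
  x <- smfbmi:::smf_stack(s$smf, s$smf$lags)$x
  base <- detect(dec, x)
  counts <- function(tm, tc) sum(base$mi_est >= tm & base$confidence >= tc)
  tms <- quantile(base$mi_est, seq(0, 1, 0.1))
  tcs <- quantile(base$confidence, seq(0, 1, 0.1))
  for (tc in tcs) expect_true(all(diff(sapply(tms, counts, tc = tc)) <= 0))
  for (tm in tms) expect_true(all(diff(sapply(tcs, function(tc) counts(tm, tc))) <= 0))
})
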