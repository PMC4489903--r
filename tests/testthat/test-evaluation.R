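test_that("nested CV is unbiased on null data and perfect on separable data", {
  nul <- null_smf(n_per = 10, d = 6, lags = seq(-200, 200, 100), seed = 60)
  rep_null <- nested_cv_accuracy(nul, outer_folds = 5, inner_repeats = 3,
                                 cost_grid = 1, gamma_grid = 0.02, seed = 61)
  band <- qbinom(c(0.005, 0.995), 20, 0.5) / 20
  expect_gte(rep_null$pooled_accuracy, band[1])
  expect_lte(rep_null$pooled_accuracy, band[2])

  sep <- separable_smf(peak = 0, margin = 8, noise = 0.05, seed = 62)
  rep_sep <- nested_cv_accuracy(sep, outer_folds = 5, inner_repeats = 2,
                                seed = 63)
  expect_equal(rep_sep$pooled_accuracy, 1)
  expect_equal(sort(unique(rep_sep$fold_assignment)), 1:5)
  expect_error(nested_cv_accuracy(separable_smf(n_per = 4), seed = 1),
               "at least")
})

test_that("inner selections never depend on the outer test trials", {
  smf <- separable_smf(n_per = 10, d = 6, lags = seq(-200, 200, 100),
                       margin = 2, noise = 1, seed = 64)
  r1 <- nested_cv_accuracy(smf, outer_folds = 5, inner_repeats = 2,
                           cost_grid = c(1, 8), gamma_grid = c(0.02, 0.2),
                           seed = 65)
  # corrupt the features of fold 1's *test* trials and rerun: fold 1's
  # inner selection, which never sees them, must be unchanged (other
  # folds legitimately change, since those trials are in their training
  # sets)
  corrupt <- smf
  f1 <- which(r1$fold_assignment == 1)
  corrupt$values[f1, , ] <- 1e3 * matrix(rnorm(length(f1) * 6 * 5),
                                         length(f1))
  r2 <- nested_cv_accuracy(corrupt, outer_folds = 5, inner_repeats = 2,
                           cost_grid = c(1, 8), gamma_grid = c(0.02, 0.2),
                           seed = 65)
  expect_identical(r1$fold_assignment, r2$fold_assignment)
  expect_identical(r1$per_fold[1, c("lag", "cost", "gamma", "inner_accuracy")],
                   r2$per_fold[1, c("lag", "cost", "gamma", "inner_accuracy")])
})

test_that("nested CV plus the binomial test keeps nominal type-I error on nulls", {
  # scaled-down null pipeline: 20 trials, 3 lags, single hyperparameter
  rejections <- 0
  n_sim <- 60
  for (i in seq_len(n_sim)) {
    nul <- null_smf(n_per = 10, d = 5, lags = c(-100, 0, 100), seed = 600 + i)
    r <- nested_cv_accuracy(nul, outer_folds = 5, inner_folds = 5,
                            inner_repeats = 2, cost_grid = 1,
                            gamma_grid = 0.02, seed = 700 + i)
    p <- binomial_test_vs_chance(r$n_correct, r$n_trials)
    if (p < 0.05) rejections <- rejections + 1
  }
  # allow the nominal 5% rate up to its 99.9% binomial envelope
  expect_lte(rejections, qbinom(0.999, n_sim, 0.05))
})

test_that("onset-detection CV concentrates detections near t_star on strong signal", {
  s <- hi_session()
  oe <- evaluate_onset_cv(s$smf, folds = 6, seed = 66,
                          d_off_grid = c(400, 600), d_on_grid = c(200, 400),
                          theta_probs = c(0.3, 0.5, 0.7))
  expect_false(oe$degenerate)
  expect_gte(oe$n_onset_range / oe$n_trials, 0.9)
  hist_mass <- sum(oe$detection_rate)
  expect_equal(hist_mass, 1, tolerance = 1e-12)
  oe2 <- evaluate_onset_cv(s$smf, folds = 6, seed = 66,
                           d_off_grid = c(400, 600), d_on_grid = c(200, 400),
                           theta_probs = c(0.3, 0.5, 0.7))
  expect_identical(oe$first_detection, oe2$first_detection)
})

test_that("forcing infinite thresholds yields a degenerate all-not-detected report", {
  s <- hi_session()
  oe <- suppressWarnings(
    evaluate_onset_cv(s$smf, folds = 6, seed = 67,
                      d_off_grid = 600, d_on_grid = 400,
                      theta_mi_fixed = Inf, theta_conf_fixed = Inf))
  expect_true(oe$degenerate)
  expect_equal(oe$n_not_detected, oe$n_trials)
  expect_true(all(is.na(oe$first_detection)))
  expect_equal(sum(oe$detection_rate), 1, tolerance = 1e-12)
})

test_that("the binomial test equals the exact tail sum", {
  expect_equal(binomial_test_vs_chance(40, 40), 0.5^40, tolerance = 1e-12)
  expect_gt(binomial_test_vs_chance(20, 40), 0.5)
  tail_oracle <- sum(choose(40, 30:40) * 0.5^40)
  expect_equal(binomial_test_vs_chance(30, 40), tail_oracle,
               tolerance = 1e-12)
  expect_error(binomial_test_vs_chance(41, 40), "n_correct")
})

test_that("the one-sided Fisher test equals hypergeometric enumeration", {
  expect_warning(p0 <- fisher_exact_one_sided(matrix(c(0, 0, 5, 7), 2)),
                 "zero margin")
  expect_equal(p0, 1)
  enum_oracle <- function(tab) {
    # P(X >= a) for X hypergeometric with the table's margins
    a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    ks <- max(0, c1 - (n - r1)):min(r1, c1)
    num <- vapply(ks, function(k) choose(r1, k) * choose(n - r1, c1 - k),
                  numeric(1))
    sum(num[ks >= a]) / sum(num)
  }
  t1 <- matrix(c(5, 0, 0, 5), 2)
  expect_equal(fisher_exact_one_sided(t1), enum_oracle(t1), tolerance = 1e-12)
  t2 <- matrix(c(8, 3, 2, 7), 2)
  expect_equal(fisher_exact_one_sided(t2), enum_oracle(t2), tolerance = 1e-12)
  # invariance under swapping both rows and both columns
  expect_equal(fisher_exact_one_sided(t2), fisher_exact_one_sided(t2[2:1, 2:1]),
               tolerance = 1e-12)
  set.seed(68)
  for (i in 1:10) {
    tt <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisher_exact_one_sided(tt), enum_oracle(tt),
                 tolerance = 1e-10)
  }
})

test_that("the paired t-test matches the textbook formula and is antisymmetric", {
  a <- c(75, 80, 62, 90, 71, 66)
  b <- c(70, 78, 65, 82, 69, 60)
  res <- paired_t_two_tailed(a, b)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * pt(-abs(t_oracle), length(d) - 1)
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  rev <- paired_t_two_tailed(b, a)
  expect_equal(rev$t, -res$t, tolerance = 1e-12)
  expect_equal(rev$p, res$p, tolerance = 1e-12)
  expect_error(paired_t_two_tailed(a, a), "zero variance")
})
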