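# closed-loop stream matching the hi_session models
hi_stream <- function() {
  fixture("hi_stream", function() {
    s <- hi_session()
    generate_closed_loop(s$layout, s$source, s$mrcf,
                         session_plan("closed_loop"), seed = 50)
  })
}

hi_log <- function() {
  fixture("hi_log", function() {
    s <- hi_session()
    run_session(hi_stream()$recording, s$baseline, hi_onset(), hi_cls(),
                hi_stream()$instructions)
  })
}

test_that("the session log ticks uniformly and is deterministic", {
  log <- hi_log()
  expect_equal(nrow(log), as.integer(recording_duration(hi_stream()$recording) / 0.2))
  expect_equal(diff(log$time_s), rep(0.2, nrow(log) - 1), tolerance = 1e-9)
  s <- hi_session()
  again <- run_session(hi_stream()$recording, s$baseline, hi_onset(), hi_cls(),
                       hi_stream()$instructions)
  expect_identical(as.data.frame(log), as.data.frame(again))
  # instruction column follows the 7-s schedule
  ch <- which(diff(as.integer(factor(log$instruction))) != 0)
  expect_equal(diff(log$time_s[ch]), rep(7, length(ch) - 1), tolerance = 1e-6)
})

test_that("infinite thresholds keep the hand at rest for the whole session", {
  s <- hi_session()
  frozen <- hi_onset(); frozen$theta_mi <- Inf; frozen$theta_conf <- Inf
  log <- run_session(hi_stream()$recording, s$baseline, frozen, hi_cls(),
                     hi_stream()$instructions)
  expect_false(any(log$onset))
  expect_true(all(log$state == "rest"))
  expect_error(evaluate_accuracy(log), "no prosthetic hand movements")
})

test_that("the 1.5-s hold suppresses repeat detections even at -Inf thresholds", {
  s <- hi_session()
  eager <- hi_onset(); eager$theta_mi <- -Inf; eager$theta_conf <- -Inf
  log <- run_session(hi_stream()$recording, s$baseline, eager, hi_cls(),
                     hi_stream()$instructions)
  t_det <- log$time_s[log$onset]
  expect_gt(length(t_det), 10)
  expect_true(all(diff(t_det) >= 1.5 - 1e-9))
})

test_that("state machine invariants hold under fuzzed thresholds", {
  s <- hi_session()
  log0 <- hi_log()
  qs <- quantile(log0$mi_est, na.rm = TRUE, probs = c(0.3, 0.6, 0.9))
  qc <- quantile(log0$confidence, na.rm = TRUE, probs = c(0.3, 0.6, 0.9))
  set.seed(51)
  for (i in 1:6) {
    dec <- hi_onset()
    dec$theta_mi <- sample(qs, 1) * runif(1, 0.8, 1.2)
    dec$theta_conf <- sample(qc, 1) * runif(1, 0.8, 1.2)
    log <- run_session(hi_stream()$recording, s$baseline, dec, hi_cls(),
                       hi_stream()$instructions)
    expect_equal(nrow(log),
                 as.integer(recording_duration(hi_stream()$recording) / 0.2))
    t_det <- log$time_s[log$onset]
    if (length(t_det) > 1) expect_true(all(diff(t_det) >= 1.5 - 1e-9))
    if (length(t_det) > 0) {
      last <- max(t_det)
      after <- log$time_s >= last + 20
      if (any(after)) expect_true(all(log$state[after] == "rest"))
      between <- log$time_s > last & log$time_s < last + 20
      expect_true(all(log$state[between] != "rest"))
    }
  }
})

test_that("a compliant high-SNR subject controls the virtual hand accurately", {
  s <- hi_session()
  accs <- vapply(50:52, function(sd) {
    stream <- generate_closed_loop(s$layout, s$source, s$mrcf,
                                   session_plan("closed_loop"), seed = sd)
    log <- run_session(stream$recording, s$baseline, hi_onset(), hi_cls(),
                       stream$instructions)
    evaluate_accuracy(log)$accuracy_pct
  }, numeric(1))
  expect_gte(mean(accs), 90)
  sel <- evaluate_selectivity(hi_log())
  expect_equal(sum(sel$table), 22)
})

test_that("movement accuracy counts state changes triggered by detections", {
  # 12 movements, 10 matching the active instruction -> 83.3%
  instr <- event_table(2 + 7 * 0:21, rep_len(c("grasp", "open"), 22), 7)
  mv <- data.frame(
    time_s = 2 + 7 * 0:11 + 1,
    predicted = rep_len(c("grasp", "open"), 12),
    stringsAsFactors = FALSE)
  mv$predicted[c(4, 9)] <- c("rest", "rest") # wrong moves: state change, wrong type
  log <- make_log(mv, duration_s = 160, instructions = instr)
  acc <- evaluate_accuracy(log)
  expect_equal(acc$n_movements, 12)
  expect_equal(acc$n_correct, 10)
  expect_equal(round(acc$accuracy_pct, 1), 83.3)

  all_ok <- make_log(mv[c(1, 2, 3), ], duration_s = 160, instructions = instr)
  expect_equal(evaluate_accuracy(all_ok)$accuracy_pct, 100)
})

test_that("selectivity partitions sections by instruction vs hand state", {
  instr <- event_table(2 + 7 * 0:9, rep_len(c("grasp", "open"), 10), 7)
  # perfect subject: hand always moves to the instruction; every section
  # is different-state (previous state != new instruction) and detected
  mv <- data.frame(time_s = 2 + 7 * 0:9 + 1,
                   predicted = rep_len(c("grasp", "open"), 10),
                   stringsAsFactors = FALSE)
  log <- make_log(mv, duration_s = 75, instructions = instr)
  expect_error(evaluate_selectivity(log), "same-state")

  # wrong-type moves in sections 3 and 7 leave the hand matching the
  # *next* instruction (same-state), where the subject then stays silent
  mv2 <- mv
  mv2$predicted[c(3, 7)] <- "open"
  mv2 <- mv2[-c(4, 8), ]
  log2 <- make_log(mv2, duration_s = 75, instructions = instr)
  sel <- evaluate_selectivity(log2)
  expect_equal(sel$sensitivity, 1)
  expect_equal(sel$specificity, 1)
  expect_equal(sel$fisher_p,
               fisher_exact_one_sided(sel$table), tolerance = 1e-12)
  expect_lt(sel$fisher_p, 0.05)
})
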