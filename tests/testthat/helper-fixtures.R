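# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small open-loop pipeline: 12 sensors, 24 trials, 12-s baseline.
small_session <- function(noise_sd = 0.3, seed = 101, n_cues = 24,
                          n_sensors = 12, lags = seq(-2000, 1000, 100)) {
  lay <- sensor_layout(n_sensors)
  src <- source_model(lay, 6)
  mr <- mrcf_params(noise_sd = noise_sd)
  plan <- session_plan(n_cues = n_cues, rest_duration_s = 12)
  ol <- generate_open_loop(lay, src, mr, plan, seed = seed)
  rest <- meg_recording(ol$recording$signal[, 1:12000], 1000, lay$labels)
  bl <- compute_baseline_stats(rest, n_windows = 12)
  smf <- compute_smf_epochs(ol$recording, ol$events, bl, lags = lags)
  list(layout = lay, source = src, mrcf = mr, plan = plan,
       recording = ol$recording, events = ol$events,
       baseline = bl, smf = smf)
}

# Default-scale session (84 sensors, 40 trials) as the generators define it.
default_session <- function(seed, noise_sd = NULL) {
  lay <- fixture("layout84", function() sensor_layout())
  src <- fixture("source84", function() source_model(fixture("layout84", sensor_layout)))
  mr <- if (is.null(noise_sd)) mrcf_params() else mrcf_params(noise_sd = noise_sd)
  ol <- generate_open_loop(lay, src, mr, seed = seed)
  rest <- meg_recording(ol$recording$signal[, 1:50000], 1000, lay$labels)
  bl <- compute_baseline_stats(rest)
  smf <- compute_smf_epochs(ol$recording, ol$events, bl)
  list(layout = lay, source = src, mrcf = mr, recording = ol$recording,
       events = ol$events, baseline = bl, smf = smf)
}

# Bare smf_set built directly from an array (for decoder unit tests).
make_smf_set <- function(values, lags, labels,
                         channels = sprintf("C%02d", seq_len(dim(values)[2]))) {
  structure(list(values = values, lags = lags, window_ms = 500,
                 labels = factor(labels), channels = channels,
                 feature = "smf"),
            class = "smf_set")
}

# Two-class set separable along feature 1 at lag `peak`, noise elsewhere.
separable_smf <- function(n_per = 10, d = 8, lags = seq(-400, 400, 100),
                          peak = 0, margin = 6, noise = 0.1, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per
    vals <- array(rnorm(n * d * length(lags), sd = noise),
                  c(n, d, length(lags)))
    j <- match(peak, lags)
    vals[seq_len(n_per), 1, j] <- vals[seq_len(n_per), 1, j] + margin
    make_smf_set(vals, lags, rep(c("grasp", "open"), each = n_per))
  })
}

# Pure-noise set with balanced labels unrelated to the features.
null_smf <- function(n_per = 20, d = 10, lags = seq(-500, 500, 100),
                     seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per
    vals <- array(rnorm(n * d * length(lags)), c(n, d, length(lags)))
    make_smf_set(vals, lags, rep_len(c("grasp", "open"), n))
  })
}

# High-SNR small-session fixtures shared by the onset-decoder and
# closed-loop tests.
hi_session <- function() {
  fixture("hi_session", function() {
    lay <- sensor_layout(12)
    src <- source_model(lay, 6)
    # two contralateral dipoles: the types differ by topography as well
    # as amplitude, so they are discriminable at any ramp phase
    mr <- mrcf_params(noise_sd = 0.1, dipole_vertex = 1,
                      dipole_vertex_open = 4)
    plan <- session_plan(n_cues = 24, rest_duration_s = 12)
    ol <- generate_open_loop(lay, src, mr, plan, seed = 27)
    rest <- meg_recording(ol$recording$signal[, 1:12000], 1000, lay$labels)
    bl <- compute_baseline_stats(rest, n_windows = 12)
    smf <- compute_smf_epochs(ol$recording, ol$events, bl)
    list(layout = lay, source = src, mrcf = mr, plan = plan,
         recording = ol$recording, events = ol$events,
         baseline = bl, smf = smf)
  })
}
hi_course <- function() {
  fixture("hi_course", function() compute_mi_course(hi_session()$smf, seed = 28))
}
hi_cls <- function() {
  fixture("hi_cls", function() train_class_decoder(hi_session()$smf, seed = 32))
}
hi_onset <- function() {
  fixture("hi_onset", function() {
    smf <- hi_session()$smf
    tt <- select_time_triple(smf, hi_course(), hi_cls()$t_star)
    est <- train_mi_estimator(smf, tt$triple, hi_course())
    optimize_onset_params(smf, hi_cls(), est, time_triple = tt$triple,
                          d_off_grid = c(400, 600), d_on_grid = c(300, 500))
  })
}

# Hand-built closed-loop log for the evaluation metrics: `movements` is a
# data.frame with columns time_s, predicted, instruction (the state the hand
# moves to and the instruction active at that tick).
make_log <- function(movements, duration_s = 160, tick_s = 0.2,
                     instructions = NULL) {
  if (is.null(instructions))
    instructions <- event_table(2 + 7 * 0:21,
                                rep_len(c("grasp", "open"), 22), 7)
  n <- as.integer(duration_s / tick_s)
  times <- tick_s * seq_len(n)
  log <- data.frame(tick = seq_len(n), time_s = times,
                    mi_est = NA_real_, confidence = NA_real_,
                    onset = FALSE, predicted = NA_character_,
                    state = NA_character_, instruction = NA_character_,
                    stringsAsFactors = FALSE)
  state <- "rest"
  for (k in seq_len(n)) {
    i <- which(abs(movements$time_s - times[k]) < tick_s / 4)
    if (length(i) == 1) {
      log$onset[k] <- TRUE
      log$predicted[k] <- movements$predicted[i]
      state <- movements$predicted[i]
    }
    log$state[k] <- state
    j <- findInterval(times[k], instructions$onset)
    log$instruction[k] <- if (j == 0) NA_character_ else
      instructions$trial_type[j]
  }
  structure(log, class = c("closed_loop_log", "data.frame"),
            tick_s = tick_s, hold_s = 1.5, idle_timeout_s = 20,
            feature_latency_s = 0.35, instructions = instructions)
}
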