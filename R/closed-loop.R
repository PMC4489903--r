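#' Run a simulated closed-loop session
#'
#' Streams a recording through the onset and class decoders exactly as
#' the online system would: every 200 ms the SMF is computed from the
#' trailing 500-ms window, the onset decoder is evaluated, and on a
#' detection the virtual prosthetic hand moves to the movement type
#' inferred by the class decoder. After a detection the hand holds its
#' state for 1.5 s, during which further detections are suppressed
#' (before logging). If no onset is detected for 20 s, the hand returns
#' to its resting position.
#'
#' Ticks are evaluated at `tick_s` intervals over the whole stream; the
#' few ticks before one full feature window has elapsed are logged with
#' missing feature values and cannot detect. The log header records the
#' feature-path latency implied by the window and tick cadence; it is
#' reported only and never used in decoding.
#'
#' @param stream a [meg_recording()] (the closed-loop stream).
#' @param baseline `baseline_stats` from the open-loop rest period.
#' @param onset_decoder a trained `onset_decoder`.
#' @param class_decoder a trained `class_decoder`.
#' @param instructions data.frame with `onset` (s) and `trial_type`
#'   (the instruction schedule); must end within the stream.
#' @param tick_s decoder update period (default 0.2 s).
#' @param hold_s hold duration after a detection (default 1.5 s).
#' @param idle_timeout_s return-to-rest timeout (default 20 s).
#' @param window_ms SMF window (default 500).
#' @param channel_subset channels used by the decoders (default all).
#' @return A `closed_loop_log`: data.frame with one row per tick
#'   (`tick`, `time_s`, `mi_est`, `confidence`, `onset`, `predicted`,
#'   `state`, `instruction`), with the session parameters in
#'   attributes.
#' @export
run_session <- function(stream, baseline, onset_decoder, class_decoder,
                        instructions, tick_s = 0.2, hold_s = 1.5,
                        idle_timeout_s = 20, window_ms = 500,
                        channel_subset = NULL) {
  stopifnot(inherits(stream, "meg_recording"),
            inherits(onset_decoder, "onset_decoder"),
            inherits(class_decoder, "class_decoder"))
  dur <- recording_duration(stream)
  if (max(instructions$onset) >= dur)
    stop("instruction schedule extends beyond the stream")
  if (dur < window_ms / 1000 + tick_s)
    stop("stream shorter than one feature window plus one tick")
  srate <- stream$srate
  n_ticks <- as.integer(floor(dur / tick_s + 1e-9))
  times <- tick_s * seq_len(n_ticks)
  instr_at <- function(t) {
    k <- findInterval(t, instructions$onset)
    if (k == 0) NA_character_ else instructions$trial_type[k]
  }
  log <- data.frame(tick = seq_len(n_ticks), time_s = times,
                    mi_est = NA_real_, confidence = NA_real_,
                    onset = FALSE, predicted = NA_character_,
                    state = NA_character_, instruction = NA_character_,
                    stringsAsFactors = FALSE)
  state <- "rest"
  hold_until <- -Inf
  last_detection <- -Inf
  wlen_s <- window_ms / 1000
  for (k in seq_len(n_ticks)) {
    t <- times[k]
    if (t >= wlen_s - 1e-9) {
      i1 <- time_to_sample(t, srate) - 1L
      i0 <- i1 - as.integer(round(wlen_s * srate)) + 1L
      v <- stream_smf(stream$signal[, i0:i1, drop = FALSE], baseline,
                      srate, window_ms, channel_subset)
      d <- detect(onset_decoder, v)
      log$mi_est[k] <- d$mi_est
      log$confidence[k] <- d$confidence
      if (t < hold_until) {
        # hold period: detections suppressed before logging
      } else if (d$onset) {
        pred <- as.character(predict(class_decoder, v))
        log$onset[k] <- TRUE
        log$predicted[k] <- pred
        state <- pred
        last_detection <- t
        hold_until <- t + hold_s
      } else if (t - last_detection >= idle_timeout_s) {
        state <- "rest"
      }
    }
    log$state[k] <- state
    log$instruction[k] <- instr_at(t)
  }
  structure(log,
            class = c("closed_loop_log", "data.frame"),
            tick_s = tick_s, hold_s = hold_s,
            idle_timeout_s = idle_timeout_s,
            feature_latency_s = wlen_s / 2 + tick_s / 2,
            instructions = instructions)
}

#' Closed-loop movement accuracy
#'
#' A prosthetic-hand movement is a state change triggered by a
#' detection; it is correct when the new state equals the instruction
#' active at the detection tick. The accuracy is correct movements over
#' all movements, as a percentage.
#'
#' @param log a `closed_loop_log`.
#' @return List with `accuracy_pct`, `n_correct`, `n_movements`.
#' @export
evaluate_accuracy <- function(log) {
  prev_state <- c("rest", log$state[-nrow(log)])
  moved <- log$onset & log$state != prev_state
  if (!any(moved))
    stop("no prosthetic hand movements in the log; accuracy undefined")
  correct <- moved & !is.na(log$instruction) &
    log$state == log$instruction
  list(accuracy_pct = 100 * sum(correct) / sum(moved),
       n_correct = sum(correct), n_movements = sum(moved))
}

#' Closed-loop detection selectivity
#'
#' Splits the session into one section per instruction interval and
#' classifies each as "same state" (the hand already matches the new
#' instruction at the moment it appears: no movement needed) or
#' "different state" (a movement is required). Sensitivity is the
#' fraction of different-state sections containing at least one
#' detection; specificity is the fraction of same-state sections
#' containing none. Selectivity is tested with a one-sided Fisher's
#' exact test for detections being enriched in different-state
#' sections.
#'
#' @param log a `closed_loop_log`.
#' @return List with `sensitivity`, `specificity`, `fisher_p`, and the
#'   underlying 2x2 `table` (rows: different/same state; columns:
#'   detected/undetected sections).
#' @export
evaluate_selectivity <- function(log) {
  instructions <- attr(log, "instructions")
  ends <- c(instructions$onset[-1], max(log$time_s) + 1e-9)
  n_sec <- nrow(instructions)
  same <- logical(n_sec); detected <- logical(n_sec)
  for (i in seq_len(n_sec)) {
    before <- log$time_s < instructions$onset[i]
    state0 <- if (any(before)) log$state[max(which(before))] else "rest"
    same[i] <- state0 == instructions$trial_type[i]
    in_sec <- log$time_s >= instructions$onset[i] & log$time_s < ends[i]
    detected[i] <- any(log$onset[in_sec])
  }
  if (all(same) || !any(same))
    stop("both same-state and different-state sections are required")
  tab <- matrix(c(sum(!same & detected), sum(!same & !detected),
                  sum(same & detected), sum(same & !detected)),
                nrow = 2, byrow = TRUE,
                dimnames = list(state = c("different", "same"),
                                detection = c("detected", "undetected")))
  list(sensitivity = sum(!same & detected) / sum(!same),
       specificity = sum(same & !detected) / sum(same),
       fisher_p = fisher_exact_one_sided(tab),
       table = tab)
}

#' Write a closed-loop log as TSV plus a JSON summary
#'
#' @param log a `closed_loop_log`.
#' @param path TSV path; the summary is written next to it with suffix
#'   `_summary.json`.
#' @return `path`, invisibly.
#' @export
write_closed_loop_log <- function(log, path) {
  utils::write.table(as.data.frame(log), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(tick_s = attr(log, "tick_s"),
                  hold_s = attr(log, "hold_s"),
                  idle_timeout_s = attr(log, "idle_timeout_s"),
                  feature_latency_s = attr(log, "feature_latency_s"),
                  n_detections = sum(log$onset))
  acc <- tryCatch(evaluate_accuracy(log), error = function(e) NULL)
  sel <- tryCatch(evaluate_selectivity(log), error = function(e) NULL)
  if (!is.null(acc)) summary <- c(summary, acc)
  if (!is.null(sel)) summary <- c(summary, sel[c("sensitivity",
                                                 "specificity", "fisher_p")])
  jsonlite::write_json(summary, paste0(sub("\\.tsv$", "", path),
                                       "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
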