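#' Movement-related cortical field parameters
#'
#' Parameters of the synthetic movement-related cortical field (MRCF):
#' a smooth unimodal source waveform that ramps up before the execution
#' cue and peaks around movement, with an amplitude that depends on the
#' movement type. The waveform is a half-Gaussian rise from `ramp_start`
#' to `peak_time` followed by a symmetric half-Gaussian decay over
#' `decay_ms` (each half-width is a third of the corresponding span, so
#' the waveform is near zero at its edges).
#'
#' @param ramp_start ramp onset in ms relative to the cue (default -1000).
#' @param peak_time peak in ms relative to the cue (default 0).
#' @param amplitude_grasp,amplitude_open source amplitude for each
#'   movement type (arbitrary current units).
#' @param dipole_vertex index of the active vertex in the source model
#'   (default 1, a contralateral vertex).
#' @param dipole_vertex_open optional distinct vertex for the open
#'   movement; `NULL` (default) uses `dipole_vertex` for both types, so
#'   the types differ by source amplitude alone. Supplying a second
#'   vertex gives the types distinct sensor topographies in addition to
#'   their amplitude difference, removing the ramp-phase/type-amplitude
#'   confound of single-dipole coding.
#' @param noise_sd sensor noise standard deviation.
#' @param decay_ms duration of the post-peak decay (default 500).
#' @param ar1 optional AR(1) coefficient for temporally correlated
#'   sensor noise (default 0, i.i.d. noise).
#' @return An `mrcf_params` list.
#' @export
mrcf_params <- function(ramp_start = -1000, peak_time = 0,
                        amplitude_grasp = 0.12, amplitude_open = 0.06,
                        dipole_vertex = 1L, dipole_vertex_open = NULL,
                        noise_sd = 1, decay_ms = 500, ar1 = 0) {
  if (ramp_start >= peak_time) stop("`ramp_start` must precede `peak_time`")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (decay_ms <= 0) stop("`decay_ms` must be positive")
  if (abs(ar1) >= 1) stop("`ar1` must be in (-1, 1)")
  structure(
    list(ramp_start = ramp_start, peak_time = peak_time,
         amplitude_grasp = amplitude_grasp, amplitude_open = amplitude_open,
         dipole_vertex = as.integer(dipole_vertex),
         dipole_vertex_open = if (is.null(dipole_vertex_open)) NULL else
           as.integer(dipole_vertex_open),
         noise_sd = noise_sd, decay_ms = decay_ms, ar1 = ar1),
    class = "mrcf_params"
  )
}

#' MRCF source waveform
#'
#' @param t_ms times in ms relative to the cue/peak reference.
#' @param params an [mrcf_params()].
#' @return Waveform values in `[0, 1]`, peaking at `params$peak_time`.
#' @export
mrcf_waveform <- function(t_ms, params) {
  rise_sd <- (params$peak_time - params$ramp_start) / 3
  decay_sd <- params$decay_ms / 3
  w <- numeric(length(t_ms))
  pre <- t_ms >= params$ramp_start & t_ms <= params$peak_time
  post <- t_ms > params$peak_time & t_ms <= params$peak_time + params$decay_ms
  w[pre] <- exp(-(t_ms[pre] - params$peak_time)^2 / (2 * rise_sd^2))
  w[post] <- exp(-(t_ms[post] - params$peak_time)^2 / (2 * decay_sd^2))
  w
}

#' Session plan
#'
#' Describes an experimental session: an open-loop session with `n_cues`
#' execution cues in randomized blocks of `block_size` identical
#' movement types, or a closed-loop session with `n_instructions`
#' instructions alternating between grasp and open every
#' `instruction_period_s` seconds. Both start with `rest_duration_s` of
#' rest used for baseline z-scoring statistics.
#'
#' @param kind `"open_loop"` or `"closed_loop"`.
#' @param n_cues number of execution cues (open loop, default 40).
#' @param block_size cues per instruction block (default 4).
#' @param instruction_period_s seconds per instruction (closed loop,
#'   default 7).
#' @param n_instructions number of closed-loop instructions (default 22).
#' @param rest_duration_s rest period at session start (default 50).
#' @param srate sampling rate in Hz (default 1000).
#' @param iti_s inter-cue interval in the open loop (default 4).
#' @param lead_in_s rest between the baseline period (open loop) or the
#'   stream start (closed loop) and the first cue/instruction (default 3
#'   and 2 respectively).
#' @return A `session_plan` list.
#' @export
session_plan <- function(kind = c("open_loop", "closed_loop"),
                         n_cues = 40, block_size = 4,
                         instruction_period_s = 7, n_instructions = 22,
                         rest_duration_s = 50, srate = 1000,
                         iti_s = 4,
                         lead_in_s = if (match.arg(kind) == "open_loop") 3 else 2) {
  kind <- match.arg(kind)
  if (kind == "open_loop" && n_cues %% block_size != 0)
    stop("`n_cues` must be divisible by `block_size`")
  if ((n_cues / block_size) %% 2 != 0 && kind == "open_loop")
    stop("the number of blocks must be even so both movement types occur equally often")
  structure(
    list(kind = kind, n_cues = n_cues, block_size = block_size,
         instruction_period_s = instruction_period_s,
         n_instructions = n_instructions,
         rest_duration_s = rest_duration_s, srate = srate,
         iti_s = iti_s, lead_in_s = lead_in_s),
    class = "session_plan"
  )
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Sensor noise matrix: channels x samples, i.i.d. N(0, sd) or AR(1).
sensor_noise <- function(n_channels, n_samples, sd, ar1 = 0) {
  if (sd == 0) return(matrix(0, n_channels, n_samples))
  e <- matrix(stats::rnorm(n_channels * n_samples, sd = sd),
              n_channels, n_samples)
  if (ar1 != 0) {
    # innovations scaled so the marginal SD stays `sd`
    e <- e * sqrt(1 - ar1^2)
    for (j in 2:n_samples) e[, j] <- ar1 * e[, j - 1] + e[, j]
  }
  e
}

#' Generate a rest recording
#'
#' Zero-mean stationary sensor noise with no events; used to estimate
#' baseline z-scoring statistics.
#'
#' @param layout a [sensor_layout()].
#' @param duration_s duration in seconds (>= 1).
#' @param noise_sd per-sample noise SD.
#' @param seed RNG seed (integer) or `NULL` to use the current RNG state.
#' @param srate sampling rate in Hz.
#' @param ar1 AR(1) coefficient for temporally correlated noise.
#' @return A [meg_recording()].
#' @export
generate_rest <- function(layout, duration_s, noise_sd = 1, seed = NULL,
                          srate = 1000, ar1 = 0) {
  stopifnot(inherits(layout, "sensor_layout"))
  if (duration_s < 1) stop("`duration_s` must be at least 1 second")
  n <- as.integer(round(duration_s * srate))
  sig <- with_seed_if(seed,
    sensor_noise(layout$n_sensors, n, noise_sd, ar1))
  meg_recording(sig, srate, layout$labels)
}

# Randomized block order of movement types: n_blocks/2 of each type,
# order permuted.
block_type_order <- function(n_blocks) {
  types <- rep(c("grasp", "open"), each = n_blocks / 2)
  sample(types)
}

# Add leadfield-projected MRCF waveforms to a signal matrix in place.
embed_mrcf <- function(signal, srate, source, params, event_times_s, types) {
  v_open <- params$dipole_vertex_open %||% params$dipole_vertex
  gain <- list(grasp = source$leadfield[, params$dipole_vertex],
               open = source$leadfield[, v_open])
  amp <- c(grasp = params$amplitude_grasp, open = params$amplitude_open)
  t0 <- params$ramp_start / 1000
  t1 <- (params$peak_time + params$decay_ms) / 1000
  for (i in seq_along(event_times_s)) {
    cue <- event_times_s[i]
    i0 <- time_to_sample(cue + t0, srate)
    i1 <- time_to_sample(cue + t1, srate) - 1L
    idx <- max(1L, i0):min(ncol(signal), i1)
    t_ms <- ((idx - 1L) / srate - cue) * 1000
    w <- mrcf_waveform(t_ms, params) * amp[[types[i]]]
    signal[, idx] <- signal[, idx] + outer(gain[[types[i]]], w)
  }
  signal
}

#' Generate an open-loop session
#'
#' Produces a continuous recording that starts with a rest period
#' (baseline), followed by `n_cues` execution cues in randomized blocks
#' of `block_size` identical movement types. Around each cue the sensor
#' signal contains the leadfield projection of the type-dependent MRCF
#' waveform plus sensor noise.
#'
#' @param layout a [sensor_layout()].
#' @param source a [source_model()].
#' @param mrcf an [mrcf_params()].
#' @param plan a [session_plan()] with `kind = "open_loop"`.
#' @param seed RNG seed or `NULL`.
#' @return A list with elements `recording` ([meg_recording()]) and
#'   `events` (data.frame with `onset`, `duration`, `trial_type`).
#' @export
generate_open_loop <- function(layout, source, mrcf, plan = session_plan(),
                               seed = NULL) {
  stopifnot(inherits(layout, "sensor_layout"),
            inherits(source, "source_model"),
            inherits(mrcf, "mrcf_params"),
            inherits(plan, "session_plan"))
  if (plan$kind != "open_loop") stop("`plan` must have kind \"open_loop\"")
  if (max(mrcf$dipole_vertex, mrcf$dipole_vertex_open %||% 1L) >
        ncol(source$leadfield))
    stop("`dipole_vertex` exceeds the number of vertices")
  srate <- plan$srate
  cues <- plan$rest_duration_s + plan$lead_in_s +
    plan$iti_s * (seq_len(plan$n_cues) - 1)
  dur <- cues[length(cues)] + 2.5
  n <- as.integer(round(dur * srate))
  with_seed_if(seed, {
    types <- rep(block_type_order(plan$n_cues / plan$block_size),
                 each = plan$block_size)
    sig <- sensor_noise(layout$n_sensors, n, mrcf$noise_sd, mrcf$ar1)
    sig <- embed_mrcf(sig, srate, source, mrcf, cues, types)
    list(recording = meg_recording(sig, srate, layout$labels),
         events = event_table(cues, types))
  })
}

#' Generate a closed-loop session stream
#'
#' Produces a continuous recording in which instructions alternate
#' between grasp and open every `instruction_period_s` seconds. A
#' simulated subject attempts the instructed movement with probability
#' `compliance`, at a reaction latency drawn from a truncated normal
#' distribution; each attempt embeds the corresponding MRCF (peaking at
#' the attempt time) into the stream. The true attempt times and types
#' are returned for evaluation.
#'
#' @inheritParams generate_open_loop
#' @param plan a [session_plan()] with `kind = "closed_loop"`.
#' @param latency_mean,latency_sd mean and SD (s) of the reaction
#'   latency from instruction onset to movement attempt; latencies are
#'   truncated below at 0.3 s.
#' @param compliance probability that an instruction is followed.
#' @return A list with `recording`, `instructions` (data.frame `onset`,
#'   `duration`, `trial_type`) and `intents` (data.frame `onset`,
#'   `trial_type`, `instruction`): the ground-truth movement attempts.
#' @export
generate_closed_loop <- function(layout, source, mrcf,
                                 plan = session_plan("closed_loop"),
                                 latency_mean = 1, latency_sd = 0.25,
                                 compliance = 1, seed = NULL) {
  stopifnot(inherits(plan, "session_plan"))
  if (plan$kind != "closed_loop") stop("`plan` must have kind \"closed_loop\"")
  if (compliance < 0 || compliance > 1) stop("`compliance` must be in [0, 1]")
  srate <- plan$srate
  instr_on <- plan$lead_in_s +
    plan$instruction_period_s * (seq_len(plan$n_instructions) - 1)
  instr_type <- rep_len(c("grasp", "open"), plan$n_instructions)
  dur <- plan$lead_in_s + plan$instruction_period_s * plan$n_instructions
  n <- as.integer(round(dur * srate))
  with_seed_if(seed, {
    sig <- sensor_noise(layout$n_sensors, n, mrcf$noise_sd, mrcf$ar1)
    followed <- stats::runif(plan$n_instructions) < compliance
    lat <- pmax(0.3, stats::rnorm(plan$n_instructions, latency_mean, latency_sd))
    onset <- instr_on + lat
    keep <- followed & (onset + mrcf$decay_ms / 1000 < dur)
    intents <- data.frame(onset = onset[keep],
                          trial_type = instr_type[keep],
                          instruction = which(keep),
                          stringsAsFactors = FALSE)
    if (nrow(intents) > 0)
      sig <- embed_mrcf(sig, srate, source, mrcf,
                        intents$onset, intents$trial_type)
    list(recording = meg_recording(sig, srate, layout$labels),
         instructions = event_table(instr_on, instr_type,
                                    plan$instruction_period_s),
         intents = intents)
  })
}
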