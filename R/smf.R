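#' Baseline z-scoring statistics from a rest period
#'
#' Splits the start of a rest recording into `n_windows` non-overlapping
#' windows of `window_ms`, averages the signal within each window per
#' channel, and returns the per-channel mean and standard deviation of
#' those window means. These statistics normalize the slow magnetic
#' field (SMF): the quantity being z-scored is itself a window mean, so
#' the SD is taken across window means, not across raw samples.
#'
#' @param rest a [meg_recording()] of resting data.
#' @param window_ms baseline window length in ms (default 1000).
#' @param n_windows number of windows (default 50, i.e. 50 s of rest).
#' @return A `baseline_stats` list with per-channel `mean` and `sd`,
#'   plus `window_ms`, `n_windows` and `channels`.
#' @export
compute_baseline_stats <- function(rest, window_ms = 1000, n_windows = 50) {
  stopifnot(inherits(rest, "meg_recording"))
  if (n_windows < 2) stop("`n_windows` must be at least 2")
  need <- n_windows * window_ms / 1000
  if (recording_duration(rest) < need)
    stop(sprintf("rest recording too short: need %g s for %d windows of %g ms",
                 need, n_windows, window_ms))
  wlen <- window_ms / 1000
  means <- vapply(seq_len(n_windows), function(k) {
    window_means(rest$signal, rest$srate, (k - 1) * wlen, k * wlen)
  }, numeric(nrow(rest$signal)))          # channels x windows
  mu <- rowMeans(means)
  sd <- apply(means, 1, stats::sd)
  bad <- which(sd == 0)
  if (length(bad) > 0)
    stop("zero baseline SD (z-scoring undefined) for channel(s): ",
         paste(rest$channels[bad], collapse = ", "))
  structure(
    list(mean = mu, sd = sd, window_ms = window_ms, n_windows = n_windows,
         channels = rest$channels),
    class = "baseline_stats"
  )
}

default_lags <- function() seq(-2000, 1000, by = 100)

#' Epoch a recording into SMF features
#'
#' The slow magnetic field (SMF) at a lag is the per-channel mean of the
#' 500-ms signal window ending at `cue + lag`, z-scored with the
#' baseline statistics. Lags are expressed in ms relative to each
#' event's execution cue; the default grid spans -2000 to 1000 ms in
#' 100-ms steps (31 lags). Windows are causal (trailing), matching what
#' an online decoder can compute.
#'
#' @param recording a [meg_recording()].
#' @param events event data.frame with `onset` (s) and `trial_type`.
#' @param baseline a `baseline_stats` object.
#' @param lags lag grid in ms (strictly increasing).
#' @param window_ms feature window length (default 500).
#' @param channel_subset integer or character index of channels to keep
#'   (default all channels of the baseline).
#' @return An `smf_set`: list with `values` (trials x channels x lags
#'   array in z-units), `lags`, `window_ms`, `labels` (factor) and
#'   `channels`.
#' @export
compute_smf_epochs <- function(recording, events, baseline,
                               lags = default_lags(), window_ms = 500,
                               channel_subset = NULL) {
  stopifnot(inherits(recording, "meg_recording"),
            inherits(baseline, "baseline_stats"))
  if (any(diff(lags) <= 0)) stop("`lags` must be strictly increasing")
  sel <- resolve_channels(recording$channels, channel_subset)
  mu <- baseline$mean[sel]; sd <- baseline$sd[sel]
  srate <- recording$srate
  dur <- recording_duration(recording)
  starts <- outer(events$onset, lags / 1000, "+") - window_ms / 1000
  ends <- starts + window_ms / 1000
  bad <- which(apply(starts < 0 | ends > dur, 1, any))
  if (length(bad) > 0)
    stop("SMF window out of recording bounds for trial(s): ",
         paste(bad, collapse = ", "))
  n_tr <- nrow(events)
  sig <- recording$signal[sel, , drop = FALSE]
  # per-channel cumulative sums make every window mean an O(channels)
  # difference instead of a slice of the signal matrix
  cs <- matrix(0, nrow(sig), ncol(sig) + 1L)
  for (r in seq_len(nrow(sig))) cs[r, -1L] <- cumsum(sig[r, ])
  vals <- array(NA_real_, c(n_tr, length(sel), length(lags)),
                dimnames = list(NULL, recording$channels[sel], lags))
  wlen <- as.integer(round(window_ms / 1000 * srate))
  for (i in seq_len(n_tr)) {
    for (j in seq_along(lags)) {
      i0 <- time_to_sample(starts[i, j], srate)
      wm <- (cs[, i0 + wlen] - cs[, i0]) / wlen
      vals[i, , j] <- (wm - mu) / sd
    }
  }
  structure(
    list(values = vals, lags = lags, window_ms = window_ms,
         labels = factor(events$trial_type),
         channels = recording$channels[sel], feature = "smf"),
    class = "smf_set"
  )
}

#' @export
print.smf_set <- function(x, ...) {
  cat(sprintf("<%s_set> %d trials x %d %s x %d lags (%g..%g ms)\n",
              x$feature, dim(x$values)[1], dim(x$values)[2],
              if (x$feature == "smf") "channels" else "vertices",
              dim(x$values)[3], min(x$lags), max(x$lags)))
  invisible(x)
}

#' Streamed (online) SMF vector
#'
#' Computes the SMF from the trailing `window_ms` of a signal buffer
#' using the same arithmetic as [compute_smf_epochs()], so offline and
#' online values agree exactly on shared time points. Online, this is
#' evaluated every 200 ms on the latest buffer.
#'
#' @param buffer channels x samples matrix holding the most recent
#'   signal (at least `window_ms` of it).
#' @param baseline a `baseline_stats` object.
#' @param srate sampling rate of the buffer in Hz.
#' @param window_ms feature window (default 500).
#' @param channel_subset channels to keep (default all).
#' @return Named numeric vector of z-scored window means.
#' @export
stream_smf <- function(buffer, baseline, srate = 1000, window_ms = 500,
                       channel_subset = NULL) {
  stopifnot(inherits(baseline, "baseline_stats"))
  wlen <- as.integer(round(window_ms / 1000 * srate))
  if (ncol(buffer) < wlen)
    stop(sprintf("buffer holds %d samples, need at least %d", ncol(buffer), wlen))
  ch <- rownames(buffer)
  if (is.null(ch)) ch <- baseline$channels
  sel <- resolve_channels(ch, channel_subset)
  tail_idx <- (ncol(buffer) - wlen + 1L):ncol(buffer)
  wm <- rowMeans(buffer[sel, tail_idx, drop = FALSE])
  stats::setNames((wm - baseline$mean[sel]) / baseline$sd[sel], ch[sel])
}

resolve_channels <- function(channels, subset) {
  if (is.null(subset)) return(seq_along(channels))
  if (is.character(subset)) {
    sel <- match(subset, channels)
    if (anyNA(sel)) stop("unknown channel(s): ",
                         paste(subset[is.na(sel)], collapse = ", "))
    return(sel)
  }
  sel <- as.integer(subset)
  if (any(sel < 1 | sel > length(channels)))
    stop("channel index out of range")
  sel
}

# trials x channels matrix of SMF values at one lag
smf_at_lag <- function(smf, lag) {
  j <- match(lag, smf$lags)
  if (is.na(j)) stop(sprintf("lag %g ms not on the SMF lag grid", lag))
  m <- smf$values[, , j, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

# stack trials x channels matrices for several lags into one matrix
# (rows ordered trial-fastest within each lag block); returns the matrix
# plus the lag of each row
smf_stack <- function(smf, lags) {
  mats <- lapply(lags, function(l) smf_at_lag(smf, l))
  list(x = do.call(rbind, mats),
       lag = rep(lags, each = dim(smf$values)[1]),
       trial = rep(seq_len(dim(smf$values)[1]), times = length(lags)))
}
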