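#' Multichannel recording container
#'
#' A `meg_recording` holds a continuous multichannel signal as a
#' channels x samples matrix together with its sampling rate and channel
#' labels. All timing in the package is expressed in seconds from the
#' first sample of the recording; sample `i` covers the half-open time
#' interval `[(i-1)/srate, i/srate)`.
#'
#' @param signal numeric matrix, channels x samples.
#' @param srate sampling rate in Hz.
#' @param channels character vector of channel labels (defaults to
#'   `MEG001`, `MEG002`, ...).
#' @return An object of class `meg_recording`.
#' @export
meg_recording <- function(signal, srate, channels = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric channels x samples matrix")
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("`srate` must be a positive scalar (Hz)")
  if (is.null(channels))
    channels <- sprintf("MEG%03d", seq_len(nrow(signal)))
  if (length(channels) != nrow(signal))
    stop("`channels` length must equal the number of signal rows")
  rownames(signal) <- channels
  structure(
    list(signal = signal, srate = srate, channels = channels),
    class = "meg_recording"
  )
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf("<meg_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$signal), ncol(x$signal),
              ncol(x$signal) / x$srate, x$srate))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording a [meg_recording()].
#' @return Duration in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$signal) / recording$srate
}

#' Event table constructor
#'
#' Events follow the BIDS events convention: one row per event with an
#' onset in seconds from the start of the recording, a duration and a
#' trial type (here the instructed movement, `"grasp"` or `"open"`).
#'
#' @param onset numeric vector of onsets (s).
#' @param trial_type character or factor of event labels.
#' @param duration numeric vector of durations (s), recycled.
#' @return A `data.frame` with columns `onset`, `duration`, `trial_type`.
#' @export
event_table <- function(onset, trial_type, duration = 0) {
  if (length(onset) != length(trial_type))
    stop("`onset` and `trial_type` must have the same length")
  data.frame(onset = as.numeric(onset),
             duration = rep_len(as.numeric(duration), length(onset)),
             trial_type = as.character(trial_type),
             stringsAsFactors = FALSE)
}

#' Read or write a BIDS-style events TSV
#'
#' @param events a data.frame as returned by [event_table()].
#' @param path file path.
#' @return `read_events_tsv` returns the events data.frame;
#'   `write_events_tsv` returns `path` invisibly.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

# Convert a time in seconds to the index of the first sample at or after it.
time_to_sample <- function(t_s, srate) as.integer(round(t_s * srate)) + 1L

# Mean of signal over the half-open window [from_s, to_s) for each channel.
window_means <- function(signal, srate, from_s, to_s) {
  i0 <- time_to_sample(from_s, srate)
  i1 <- time_to_sample(to_s, srate) - 1L
  if (i0 < 1L || i1 > ncol(signal))
    stop(sprintf("window [%g, %g) s outside recording", from_s, to_s))
  rowMeans(signal[, i0:i1, drop = FALSE])
}
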