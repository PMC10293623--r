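#' Construct a raw multichannel recording
#'
#' Lightweight container for one continuous recording (one run): a
#' channels-by-samples matrix in microvolts plus sampling rate, channel kinds,
#' montage geometry, event markers and participant metadata.
#'
#' @param data Numeric matrix, channels x samples, microvolts; rownames are
#'   channel labels.
#' @param fs Sampling frequency in Hz.
#' @param channel_kinds Character vector ("EEG"/"EOG") parallel to the rows of
#'   `data`.
#' @param montage Montage tibble as from [standard_montage()].
#' @param events Tibble with columns `sample` (1-based sample index of cue
#'   onset), `task` and `condition`.
#' @param meta Named list of metadata (participant id, group, sex, run, task).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(data, fs, channel_kinds, montage, events,
                          meta = list()) {
  if (!is.matrix(data) || is.null(rownames(data))) {
    abort("`data` must be a channels x samples matrix with channel rownames.")
  }
  if (!all(is.finite(data))) abort("`data` must be finite everywhere.")
  if (length(channel_kinds) != nrow(data)) {
    abort("`channel_kinds` must have one entry per channel.")
  }
  if (nrow(events) > 0 &&
      (any(events$sample < 1) || any(events$sample > ncol(data)))) {
    abort("Event sample indices must lie within the recording.")
  }
  structure(
    list(data = data, fs = fs,
         channel_labels = rownames(data),
         channel_kinds = channel_kinds,
         montage = montage, events = events, meta = meta),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  if (!is.null(x$meta$participant)) {
    cat(sprintf("  participant %s (%s, %s), run %s [%s]\n",
                x$meta$participant, x$meta$group %||% "?", x$meta$sex %||% "?",
                x$meta$run %||% "?", x$meta$task %||% "?"))
  }
  invisible(x)
}

# Indices of EEG (scalp) channels.
eeg_idx <- function(raw) which(raw$channel_kinds == "EEG")

#' Coerce a raw recording to a long tibble
#'
#' @param x A `raw_recording`.
#' @param channels Optional subset of channel labels.
#' @param ... Unused.
#' @return Tibble with columns `time`, `channel`, `value` (microvolts).
#' @export
as_tibble.raw_recording <- function(x, channels = NULL, ...) {
  channels <- channels %||% x$channel_labels
  sub <- x$data[channels, , drop = FALSE]
  tibble::tibble(
    time = rep(seq_len(ncol(sub)) / x$fs, each = length(channels)),
    channel = rep(channels, times = ncol(sub)),
    value = as.vector(sub)
  )
}
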