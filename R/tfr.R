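# Time-frequency ERD/S maps: short-time Fourier spectrogram (Tukey window,
# power-spectrum scaling), averaged over kept epochs and ROI channels, then
# each frequency row expressed as percent change relative to its mean over
# the baseline time bins.

# One-sided power spectrogram of a single time series. Matches the common
# consecutive-FFT convention: segments of `nperseg` samples advancing by
# `nperseg - noverlap`, per-segment mean removal, periodic window, scaling
# 1 / sum(w)^2 with a factor 2 on all bins except DC (and Nyquist for even
# nperseg).
stft_power <- function(x, fs, nperseg, noverlap, window) {
  step <- nperseg - noverlap
  if (step < 1) abort("`noverlap` must be smaller than `segment_length`.")
  n <- length(x)
  if (nperseg > n) abort("Segment length exceeds the available samples.")
  starts <- seq(1L, n - nperseg + 1L, by = step)
  seg <- matrix(x[outer(seq_len(nperseg) - 1L, starts, `+`)],
                nrow = nperseg)
  seg <- sweep(seg, 2, colMeans(seg))            # constant detrend
  seg <- seg * window
  X <- mvfft(seg)
  nf <- nperseg %/% 2 + 1L
  P <- abs(X[seq_len(nf), , drop = FALSE])^2 / sum(window)^2
  scale2 <- rep(2, nf)
  scale2[1] <- 1
  if (nperseg %% 2 == 0) scale2[nf] <- 1
  P <- P * scale2
  list(
    freqs = (seq_len(nf) - 1L) * fs / nperseg,
    times = (starts - 1L + nperseg / 2) / fs,    # segment centres, seconds
    power = P
  )
}

#' Time-frequency ERD/S map for one ROI
#'
#' Computes a spectrogram per kept epoch and ROI channel (consecutive Fourier
#' transforms with a Tukey window, power-spectrum scaling), averages the
#' power over epochs and channels, and converts each frequency row to percent
#' change relative to its mean over the time bins whose centres fall in the
#' baseline window. At 500 Hz with the default segment length 250 and overlap
#' 225 the map has 2 Hz frequency resolution and 50 ms time step.
#'
#' @param epochs An [extract_epochs()] result (after rejection).
#' @param roi ROI name from `rois`, or a character vector of channel labels.
#' @param rois Named list of ROIs, default [roi_set()].
#' @param segment_length Samples per Fourier segment (default 250).
#' @param overlap Overlapping samples between consecutive segments
#'   (default 225).
#' @param tukey_alpha Tukey window taper fraction (default 0.25).
#' @param fmin,fmax Frequency range kept, in Hz (defaults 1 and 35).
#' @param trange Time range of the epoch used, seconds relative to cue onset
#'   (default `c(-1.5, 7)`, half-open).
#' @param baseline Baseline window for the percent-change normalization
#'   (default `c(-1.5, 0)`, half-open on bin centres).
#' @return Object of class `tf_map`: list with `roi`, `freqs` (Hz), `times`
#'   (s, bin centres), `values` (frequency x time, percent change) and
#'   `n_epochs`.
#' @export
tf_erds <- function(epochs, roi, rois = roi_set(), segment_length = 250,
                    overlap = 225, tukey_alpha = 0.25, fmin = 1, fmax = 35,
                    trange = c(-1.5, 7), baseline = c(-1.5, 0)) {
  channels <- if (length(roi) == 1 && roi %in% names(rois)) rois[[roi]] else roi
  roi_name <- if (length(roi) == 1 && roi %in% names(rois)) roi else "custom"
  missing <- setdiff(channels, epochs$channel_labels)
  if (length(missing)) {
    abort(sprintf("ROI channel(s) not in epochs: %s",
                  paste(missing, collapse = ", ")))
  }
  if (trange[1] < epochs$tmin || trange[2] > epochs$tmax) {
    abort("`trange` must lie inside the epoch window.")
  }
  times <- epoch_times(epochs)
  tix <- window_index(times, trange[1], trange[2])
  if (segment_length > length(tix)) {
    abort("Segment length exceeds the samples in `trange`.")
  }
  w <- tukey_window(segment_length, tukey_alpha, periodic = TRUE)
  kept <- which(epochs$kept)
  if (length(kept) == 0) abort("No kept epochs.")
  acc <- NULL
  for (i in kept) {
    for (ch in channels) {
      sp <- stft_power(epochs$data[i, ch, tix], epochs$fs,
                       segment_length, overlap, w)
      acc <- if (is.null(acc)) sp$power else acc + sp$power
    }
  }
  P <- acc / (length(kept) * length(channels))
  freqs <- sp$freqs
  tt <- sp$times + trange[1]
  keep_f <- freqs >= fmin & freqs <= fmax
  base_ix <- window_index(tt, baseline[1], baseline[2])
  if (length(base_ix) == 0) abort("No time bins fall in the baseline window.")
  B <- rowMeans(P[, base_ix, drop = FALSE])
  values <- 100 * (P / B - 1)
  structure(
    list(roi = roi_name, channels = channels,
         freqs = freqs[keep_f], times = tt,
         values = values[keep_f, , drop = FALSE],
         n_epochs = length(kept)),
    class = "tf_map"
  )
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> ROI %s: %d freqs (%g-%g Hz) x %d time bins (%g..%g s), %d epochs\n",
              x$roi, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times), x$n_epochs))
  invisible(x)
}

#' @export
as_tibble.tf_map <- function(x, ...) {
  tibble::tibble(
    roi = x$roi,
    freq = rep(x$freqs, times = length(x$times)),
    time = rep(x$times, each = length(x$freqs)),
    value = as.vector(x$values)
  )
}

#' Plot a time-frequency ERD/S map
#'
#' @param object A `tf_map`.
#' @param ... Unused.
#' @return A ggplot: time on x, frequency on y, percent change as fill
#'   (red = desynchronization, blue = synchronization).
#' @export
autoplot.tf_map <- function(object, ...) {
  df <- as_tibble.tf_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0,
                                  name = "ERD/S (%)") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "Time relative to cue (s)", y = "Frequency (Hz)",
                  title = sprintf("ROI %s (%d epochs)", object$roi,
                                  object$n_epochs)) +
    ggplot2::theme_minimal()
}

#' Mean of a time-frequency map over a band and time window
#'
#' Averages map values over the frequency rows inside a band and the time
#' bins inside a window; useful to compare the map against window-based
#' ERD/S estimates.
#'
#' @param tf A `tf_map`.
#' @param band `"alpha"`, `"beta"` or `c(lo, hi)`.
#' @param window Time window `c(from, to)` in seconds (bin centres,
#'   half-open).
#' @return Scalar percent change.
#' @export
tf_band_mean <- function(tf, band, window = c(2, 6)) {
  bl <- band_limits(band)
  fi <- tf$freqs >= bl["lo"] & tf$freqs <= bl["hi"]
  ti <- tf$times >= window[1] & tf$times < window[2]
  mean(tf$values[fi, ti])
}
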