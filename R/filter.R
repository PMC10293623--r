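# FIR filter design shared by the preprocessing chain, the ERD/S band-power
# stage and the rhythm synthesizer. Windowed-sinc (Hamming) design via
# signal::fir1, applied zero-phase (non-causal) by centred FFT convolution.

# Transition bandwidth rule: a quarter of the edge frequency, at least 2 Hz,
# never wider than the distance to the spectral boundary.
transition_bw <- function(edge, fs, side = c("low", "high")) {
  side <- match.arg(side)
  tb <- max(0.25 * edge, 2)
  lim <- if (side == "low") edge else fs / 2 - edge
  min(tb, lim)
}

# Symmetric odd-length bandpass kernel with -6 dB points at l_freq/h_freq.
design_fir_bandpass <- function(l_freq, h_freq, fs) {
  if (!(l_freq > 0 && l_freq < h_freq && h_freq < fs / 2)) {
    abort("Band edges must satisfy 0 < l_freq < h_freq < fs/2.")
  }
  lt <- transition_bw(l_freq, fs, "low")
  ht <- transition_bw(h_freq, fs, "high")
  n_taps <- ceiling(3.3 / min(lt, ht) * fs)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  w <- c(l_freq - lt / 2, h_freq + ht / 2) / (fs / 2)
  as.numeric(signal::fir1(n_taps - 1L, w, type = "pass"))
}

# Symmetric odd-length highpass kernel (used for the ICA working copy).
design_fir_highpass <- function(l_freq, fs) {
  if (!(l_freq > 0 && l_freq < fs / 2)) abort("Invalid highpass edge.")
  lt <- transition_bw(l_freq, fs, "low")
  n_taps <- ceiling(3.3 / lt * fs)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  as.numeric(signal::fir1(n_taps - 1L, (l_freq - lt / 2) / (fs / 2),
                          type = "high"))
}

#' Zero-phase FIR bandpass filter
#'
#' Filters every channel of a recording with a non-causal (zero net group
#' delay) windowed-sinc FIR bandpass. The kernel is a Hamming-windowed sinc
#' whose -6 dB points sit at `l_freq` and `h_freq`, with transition bands of
#' a quarter of each edge frequency (at least 2 Hz); it is applied by centred
#' convolution so the output has exactly zero lag relative to the input.
#'
#' @param raw A [raw_recording()].
#' @param l_freq,h_freq Lower/upper passband edges in Hz.
#' @return The filtered `raw_recording`.
#' @export
bandpass_fir <- function(raw, l_freq = 1, h_freq = 40) {
  h <- design_fir_bandpass(l_freq, h_freq, raw$fs)
  out <- raw
  out$data <- fft_filter_rows(raw$data, h)
  dimnames(out$data) <- dimnames(raw$data)
  out$meta$filter <- c(l_freq = l_freq, h_freq = h_freq)
  out
}
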