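# Automated ocular-artifact removal: FastICA decomposition of the EEG
# channels, then zeroing of every independent component whose time course
# correlates strongly with an EOG channel before back-projection. The
# decomposition runs on a 1 Hz high-passed working copy (drifts degrade ICA)
# while the unmixing is applied to the unmodified signal; component selection
# is a deterministic correlation rule so runs are reproducible.

# Symmetric fixed-point FastICA with tanh contrast. X: components' input,
# rows = variables (already whitened), cols = samples. Returns the
# orthogonal rotation W (sources = W %*% Xw).
fastica_rotation <- function(Xw, max_iter = 200, tol = 1e-6, seed = 1) {
  k <- nrow(Xw)
  W <- with_seed(seed, {
    qr.Q(qr(matrix(rnorm(k * k), k, k)))
  })
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  n <- ncol(Xw)
  for (it in seq_len(max_iter)) {
    S <- W %*% Xw
    G <- tanh(S)
    gprime <- rowMeans(1 - G^2)
    W_new <- sym_decorrelate(G %*% t(Xw) / n - diag(gprime) %*% W)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) break
  }
  W
}

#' Remove ocular (EOG-correlated) independent components
#'
#' Decomposes the EEG channels with FastICA and zeroes every component whose
#' time-course absolute Pearson correlation with any EOG channel reaches
#' `corr_threshold`, then back-projects. The decomposition is estimated on a
#' 1 Hz high-passed copy of the data (subsampled in time for speed); the
#' resulting unmixing is applied to the full-resolution, unfiltered signal.
#' If no component crosses the threshold the recording is returned unchanged.
#'
#' @param raw A [raw_recording()] containing EOG channels.
#' @param eog_labels Labels of the EOG channels (default `c("EOGV", "EOGH")`).
#' @param corr_threshold Absolute correlation at or above which a component is
#'   removed (default 0.7).
#' @param n_components Number of ICA components (default: EEG rank, capped
#'   at 20).
#' @param max_samples Maximum number of time points used to estimate the
#'   decomposition (strided subsample; default 50000).
#' @param seed Seed for the FastICA initialization (default 1; the component
#'   selection itself is deterministic).
#' @return List with `raw` (cleaned recording) and `report`: tibble with one
#'   row per component (`component`, `max_abs_corr`, `eog_channel`,
#'   `removed`).
#' @export
remove_ocular_components <- function(raw, eog_labels = c("EOGV", "EOGH"),
                                     corr_threshold = 0.7,
                                     n_components = NULL,
                                     max_samples = 50000, seed = 1) {
  if (!all(eog_labels %in% raw$channel_labels)) {
    abort("EOG channels not present in the recording.")
  }
  idx <- eeg_idx(raw)
  X <- raw$data[idx, , drop = FALSE]
  hp <- design_fir_highpass(1, raw$fs)
  Xf <- fft_filter_rows(X, hp)
  Ef <- fft_filter_rows(raw$data[eog_labels, , drop = FALSE], hp)

  stride <- max(1L, floor(ncol(Xf) / max_samples))
  sub <- seq(1L, ncol(Xf), by = stride)
  Xs <- Xf[, sub, drop = FALSE]
  mu <- rowMeans(Xs)
  Xs <- Xs - mu
  cv <- tcrossprod(Xs) / (ncol(Xs) - 1)
  e <- eigen(cv, symmetric = TRUE)
  rank <- sum(e$values > max(e$values) * 1e-10)
  k <- min(n_components %||% 20L, rank)
  K <- diag(1 / sqrt(e$values[seq_len(k)]), k) %*%
    t(e$vectors[, seq_len(k), drop = FALSE])           # whitening
  W <- fastica_rotation(K %*% Xs, seed = seed)
  unmix <- W %*% K                                     # k x n_eeg
  mix <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k) %*% t(W)       # n_eeg x k

  # correlate component time courses (on the filtered signal) with EOG
  S_full <- unmix %*% (Xf - rowMeans(Xf))
  cors <- abs(cor(t(S_full), t(Ef)))
  max_corr <- apply(cors, 1, max)
  which_eog <- eog_labels[apply(cors, 1, which.max)]
  removed <- max_corr >= corr_threshold

  report <- tibble::tibble(component = seq_len(k),
                           max_abs_corr = max_corr,
                           eog_channel = which_eog,
                           removed = removed)
  out <- raw
  if (any(removed)) {
    # apply the unmixing to the *unfiltered* signal, subtract removed parts
    S_raw <- unmix[removed, , drop = FALSE] %*% (X - rowMeans(X))
    out$data[idx, ] <- X - mix[, removed, drop = FALSE] %*% S_raw
  }
  out$meta$ica_removed <- which(removed)
  list(raw = out, report = report)
}
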