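# Spherical-spline channel interpolation (Perrin-style): a bad electrode's
# signal is reconstructed from the good electrodes via smoothing splines on
# the unit sphere. The spline kernel is
#   g(x) = 1/(4*pi) * sum_{n=1}^{N} (2n+1) / (n (n+1))^m * P_n(x)
# with P_n the Legendre polynomials, m the spline order (stiffness) and the
# series truncated at N terms. Interpolation weights depend only on montage
# geometry, never on the data.

# Legendre polynomials P_1..P_nmax evaluated at x (vector), by the
# three-term recurrence. Returns length(x) x nmax matrix.
legendre_upto <- function(x, nmax) {
  out <- matrix(0, nrow = length(x), ncol = nmax)
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  out[, 1] <- p_cur
  if (nmax >= 2) {
    for (n in 2:nmax) {
      p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
      out[, n] <- p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  out
}

# Spline kernel g(cos(angle)) for a matrix of cosines.
spline_g <- function(cosang, m = 4, n_terms = 50) {
  n <- seq_len(n_terms)
  coef <- (2 * n + 1) / (n * (n + 1))^m
  P <- legendre_upto(as.vector(cosang), n_terms)
  matrix(P %*% coef / (4 * pi), nrow = nrow(cosang))
}

#' Spherical-spline interpolation weights
#'
#' Computes the linear weights that reconstruct each bad electrode from the
#' good electrodes under the spherical-spline model (Legendre-series kernel
#' of order `m` truncated at `n_terms` terms, with diagonal regularization
#' `lambda`). The weights are a pure function of the montage geometry.
#'
#' @param montage Montage tibble (see [standard_montage()]).
#' @param good,bad Character vectors of channel labels.
#' @param m Spline order (stiffness), default 4.
#' @param n_terms Legendre series truncation, default 50.
#' @param lambda Diagonal regularization added to the kernel matrix,
#'   default 1e-5.
#' @return Matrix `length(bad)` x `length(good)`; bad-channel estimates are
#'   `W %*% data[good, ]`.
#' @export
spline_interpolation_weights <- function(montage, good, bad, m = 4,
                                         n_terms = 50, lambda = 1e-5) {
  if (length(good) < 4) {
    abort("Spherical-spline interpolation needs at least 4 good channels.")
  }
  pos <- as.matrix(montage[, c("x", "y", "z")])
  rownames(pos) <- montage$channel
  missing <- setdiff(c(good, bad), montage$channel)
  if (length(missing)) {
    abort(sprintf("Channels absent from montage: %s",
                  paste(missing, collapse = ", ")))
  }
  pg <- pos[good, , drop = FALSE]
  pb <- pos[bad, , drop = FALSE]
  G <- spline_g(tcrossprod(pg), m, n_terms)
  Gb <- spline_g(pb %*% t(pg), m, n_terms)
  ng <- length(good)
  # bordered system: [G + lambda*I, 1; 1', 0] [c; d] = [y; 0]
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)), c(rep(1, ng), 0))
  U <- cbind(Gb, rep(1, length(bad)))     # evaluation functionals
  W <- t(solve(A, t(U)))[, seq_len(ng), drop = FALSE]
  dimnames(W) <- list(bad, good)
  W
}

#' Detect flat channels
#'
#' Flags EEG channels whose sample standard deviation falls below a floor,
#' e.g. disconnected or saturated electrodes recording a constant value.
#'
#' @param raw A [raw_recording()].
#' @param min_std_uV Standard-deviation floor in microvolts (default 0.1).
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
detect_flat_channels <- function(raw, min_std_uV = 0.1) {
  idx <- eeg_idx(raw)
  x <- raw$data[idx, , drop = FALSE]
  n <- ncol(x)
  sds <- sqrt(pmax((rowMeans(x^2) - rowMeans(x)^2) * n / (n - 1), 0))
  names(sds)[sds < min_std_uV]
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces the listed bad EEG channels with their spherical-spline estimate
#' from the remaining good EEG channels; good channels are untouched.
#'
#' @param raw A [raw_recording()].
#' @param bad Character vector of bad EEG channel labels. Empty input returns
#'   the recording unchanged.
#' @inheritParams spline_interpolation_weights
#' @return The repaired `raw_recording`.
#' @export
interpolate_spherical_spline <- function(raw, bad, m = 4, n_terms = 50,
                                         lambda = 1e-5) {
  if (length(bad) == 0) return(raw)
  eeg <- raw$channel_labels[eeg_idx(raw)]
  if (!all(bad %in% eeg)) {
    abort("`bad` must be a subset of the EEG channels.")
  }
  good <- setdiff(eeg, bad)
  W <- spline_interpolation_weights(raw$montage, good, bad, m, n_terms, lambda)
  out <- raw
  out$data[bad, ] <- W %*% raw$data[good, , drop = FALSE]
  out$meta$interpolated <- union(raw$meta$interpolated, bad)
  out
}
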