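#' @importFrom rlang abort warn inform %||%
#' @importFrom stats fft mvfft sd var cor rnorm runif rpois pf pt ptukey setNames
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All randomness in the package funnels through
# this so that results are pure functions of the seeds passed in.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit integer range R requires.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483629) + 1L
}

#' Tukey (tapered cosine) window
#'
#' Symmetric Tukey window of length `n` with taper fraction `alpha`;
#' `periodic = TRUE` gives the DFT-even variant used for spectral analysis.
#'
#' @param n Window length in samples.
#' @param alpha Fraction of the window inside the cosine taper (0 = rectangular,
#'   1 = Hann). Default 0.25.
#' @param periodic Return the periodic (DFT-even) window instead of the
#'   symmetric one.
#' @return Numeric vector of length `n`.
#' @export
tukey_window <- function(n, alpha = 0.25, periodic = FALSE) {
  if (n < 1) abort("`n` must be >= 1.")
  if (alpha < 0 || alpha > 1) abort("`alpha` must be in [0, 1].")
  m <- if (periodic) n + 1L else n
  if (m == 1L) return(rep(1, n))
  if (alpha == 0) return(rep(1, n))
  k <- seq_len(m) - 1L
  w <- rep(1, m)
  width <- alpha * (m - 1) / 2
  lo <- k < width
  hi <- k > (m - 1) - width
  w[lo] <- 0.5 * (1 + cos(pi * (k[lo] / width - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((k[hi] - (m - 1)) / width + 1)))
  w[seq_len(n)]
}

# Zero-phase convolution of the rows of matrix `x` (channels x samples) with a
# symmetric odd-length kernel `h`. Implemented as FFT convolution with the
# group delay trimmed, equivalent to centred direct convolution with zero
# padding at the edges. Rows are processed in pairs packed into one complex
# transform (the kernel is real, so conv(x1 + i*x2, h) = y1 + i*y2), which
# halves the FFT work.
fft_filter_rows <- function(x, h) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1L)
  nh <- length(h)
  if (nh %% 2L == 0L) abort("Kernel must have odd length for zero-phase use.")
  ns <- ncol(x)
  nr <- nrow(x)
  nfft <- stats::nextn(ns + nh - 1L, c(2L, 3L, 5L))
  H <- fft(c(h, rep(0, nfft - nh)))
  odd <- seq(1L, nr, by = 2L)
  even <- odd + 1L
  has_partner <- even <= nr
  xt <- t(x)
  xi <- matrix(0, ns, length(odd))
  xi[, has_partner] <- xt[, even[has_partner], drop = FALSE]
  Z <- matrix(0i, nfft, length(odd))
  Z[seq_len(ns), ] <- complex(real = xt[, odd, drop = FALSE],
                              imaginary = xi)
  y <- mvfft(mvfft(Z) * H, inverse = TRUE) / nfft
  delay <- (nh - 1L) %/% 2L
  y <- y[(delay + 1L):(delay + ns), , drop = FALSE]
  out <- matrix(0, nr, ns)
  out[odd, ] <- t(Re(y))
  out[even[has_partner], ] <- t(Im(y[, has_partner, drop = FALSE]))
  if (single) drop(out) else out
}

# Sample indices (1-based) whose times fall in the half-open window
# [from, to). `times` are seconds relative to the epoch/recording origin.
window_index <- function(times, from, to) {
  which(times >= from & times < to)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
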