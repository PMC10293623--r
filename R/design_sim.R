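# Table-level simulators for validating the ANOVA layer: balanced ROI x
# condition designs with a known covariance structure, under the global null
# or with injected effects. These operate directly on the long design table
# (no signal synthesis), so large Monte-Carlo runs stay cheap.

# Non-spherical within-subject covariance over the roi x condition cells:
# heterogeneous variances with AR(1)-like correlation along ROI, Kronecker
# with a condition factor, plus a subject random intercept added separately.
default_within_cov <- function(k_roi = 6, k_cond = 3, rho = 0.5) {
  v_roi <- seq(1, 2, length.out = k_roi)
  R_roi <- rho^abs(outer(seq_len(k_roi), seq_len(k_roi), `-`))
  S_roi <- sqrt(v_roi) %o% sqrt(v_roi) * R_roi
  R_cond <- rho^abs(outer(seq_len(k_cond), seq_len(k_cond), `-`))
  S_roi %x% R_cond
}

#' Simulate a balanced long design table
#'
#' Draws one complete ROI x condition x participant table with handedness and
#' sex as balanced between-subject factors: per-subject values are a random
#' intercept plus correlated within-subject noise with a non-spherical
#' covariance, plus optional fixed cell effects. With `effects = NULL` the
#' table satisfies the global null.
#'
#' @param n_per_cell Participants per handedness x sex cell (default 7,
#'   i.e. 28 participants).
#' @param effects Optional k_roi x k_cond matrix of fixed cell means added to
#'   every subject (row/column order follows sorted factor levels).
#' @param sd_subject Standard deviation of the subject random intercept
#'   (default 8, percent ERD/S scale).
#' @param within_cov Within-subject covariance of the 18 cells (default a
#'   heterogeneous AR(1)-by-ROI Kronecker structure scaled by `sd_within^2`).
#' @param sd_within Scale of the within-subject noise (default 10).
#' @param seed Integer seed.
#' @return Long tibble with columns `participant`, `handedness`, `sex`,
#'   `roi`, `condition`, `erds_percent`.
#' @export
simulate_design_table <- function(n_per_cell = 7, effects = NULL,
                                  sd_subject = 8, within_cov = NULL,
                                  sd_within = 10, seed = 1) {
  k_roi <- 6L
  k_cond <- 3L
  rois <- sort(c("FL", "FR", "CL", "CR", "PL", "PR"))
  conds <- sort(c("BOTH", "LEFT", "RIGHT"))
  S <- within_cov %||% (default_within_cov(k_roi, k_cond) * sd_within^2)
  L <- t(chol(S))
  if (is.null(effects)) effects <- matrix(0, k_roi, k_cond)
  cells <- tidyr::expand_grid(handedness = c("left", "right"),
                              sex = c("female", "male"))
  n_sub <- 4L * n_per_cell
  p <- k_roi * k_cond
  with_seed(seed, {
    noise <- L %*% matrix(rnorm(p * n_sub), p, n_sub)       # cells x subjects
    y <- as.vector(noise + as.vector(t(effects))) +          # roi-major order
      rep(rnorm(n_sub, 0, sd_subject), each = p)
    tibble::tibble(
      participant = rep(sprintf("S%03d", seq_len(n_sub)), each = p),
      handedness = rep(rep(cells$handedness, each = n_per_cell), each = p),
      sex = rep(rep(cells$sex, each = n_per_cell), each = p),
      roi = rep(rep(rois, each = k_cond), times = n_sub),
      condition = rep(rep(conds, times = k_roi), times = n_sub),
      erds_percent = y
    )
  })
}
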