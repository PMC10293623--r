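#' Idealized spherical 10-20 montage (32 EEG + 2 EOG channels)
#'
#' Electrode positions on the unit sphere for the standard 32-channel layout
#' used throughout the package, plus two ocular channels near the left eye.
#' Positions are idealized 10-20 coordinates built from 10%-arc geometry:
#' `polar_deg` is the inclination from the vertex (Cz = 0) and `azimuth_deg`
#' the angle from the anterior midline, positive toward the right ear. The
#' layout is exactly left-right mirror symmetric, which downstream code relies
#' on (ROI mirroring, hemisphere-targeted effect injection).
#'
#' @return A tibble with columns `channel`, `kind` ("EEG"/"EOG"),
#'   `polar_deg`, `azimuth_deg` and unit-sphere Cartesian `x` (right),
#'   `y` (anterior), `z` (superior).
#' @export
#' @examples
#' m <- standard_montage()
#' all(abs(m$x^2 + m$y^2 + m$z^2 - 1) < 1e-12)
standard_montage <- function() {
  def <- list(
    # label        polar  azimuth
    c("Fp1",  72, -18), c("Fp2",  72,  18),
    c("F7",   72, -54), c("F3",   54, -45), c("Fz", 36, 0),
    c("F4",   54,  45), c("F8",   72,  54),
    c("FT9",  90, -72), c("FC5",  63, -72), c("FC1", 30, -36),
    c("FC2",  30,  36), c("FC6",  63,  72), c("FT10", 90, 72),
    c("T7",   90, -90), c("C3",   36, -90), c("Cz",  0, 0),
    c("C4",   36,  90), c("T8",   90,  90),
    c("TP9",  90, -108), c("CP5", 63, -108), c("CP1", 30, -144),
    c("CP2",  30, 144), c("CP6",  63, 108), c("TP10", 90, 108),
    c("P7",   72, -126), c("P3",  54, -135), c("Pz", 36, 180),
    c("P4",   54, 135), c("P8",   72, 126),
    c("O1",   72, -162), c("Oz",  72, 180), c("O2", 72, 162),
    c("EOGV", 108, -18), c("EOGH", 100, -45)
  )
  channel <- vapply(def, `[`, character(1), 1L)
  polar <- as.numeric(vapply(def, `[`, character(1), 2L))
  azimuth <- as.numeric(vapply(def, `[`, character(1), 3L))
  pr <- polar * pi / 180
  ar <- azimuth * pi / 180
  tibble::tibble(
    channel = channel,
    kind = ifelse(startsWith(channel, "EOG"), "EOG", "EEG"),
    polar_deg = polar,
    azimuth_deg = azimuth,
    x = sin(pr) * sin(ar),
    y = sin(pr) * cos(ar),
    z = cos(pr)
  )
}

#' Default regions of interest
#'
#' The six electrode groupings over which channel-level ERD/S values are
#' averaged: frontal, central and parietal, split by hemisphere.
#'
#' @return Named list of character vectors of channel labels: `FL`, `FR`,
#'   `CL`, `CR`, `PL`, `PR`.
#' @export
roi_set <- function() {
  list(
    FL = c("Fp1", "F3", "F7"),
    FR = c("Fp2", "F4", "F8"),
    CL = c("FC1", "FC5", "C3", "CP1", "CP5"),
    CR = c("FC2", "FC6", "C4", "CP2", "CP6"),
    PL = c("P3", "P7", "O1"),
    PR = c("P4", "P8", "O2")
  )
}

# Check that ROIs are disjoint and all members exist in the montage.
validate_roi_set <- function(rois, montage = standard_montage()) {
  all_ch <- unlist(rois, use.names = FALSE)
  if (anyDuplicated(all_ch)) {
    abort(sprintf("ROIs must be disjoint; duplicated channel(s): %s",
                  paste(unique(all_ch[duplicated(all_ch)]), collapse = ", ")))
  }
  missing <- setdiff(all_ch, montage$channel)
  if (length(missing)) {
    abort(sprintf("ROI channels absent from montage: %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(rois)
}

# Channels of one hemisphere's central ROI, used when injecting
# hemisphere-specific band-power modulation.
hemisphere_channels <- function(hemisphere) {
  switch(hemisphere,
    left = roi_set()$CL,
    right = roi_set()$CR,
    abort(sprintf("Unknown hemisphere '%s' (use 'left' or 'right').", hemisphere))
  )
}
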