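#' Frequency band definitions
#'
#' The two analysis bands: alpha/mu 8-13 Hz and beta 16-24 Hz.
#'
#' @return Tibble with columns `band`, `lo`, `hi`.
#' @export
band_defs <- function() {
  tibble::tibble(band = c("alpha", "beta"), lo = c(8, 16), hi = c(13, 24))
}

# Resolve a band given as a name ("alpha"/"beta") or c(lo, hi).
band_limits <- function(band) {
  if (is.character(band)) {
    row <- band_defs()[band_defs()$band == band, ]
    if (nrow(row) == 0) abort(sprintf("Unknown band '%s'.", band))
    c(lo = row$lo, hi = row$hi)
  } else if (is.numeric(band) && length(band) == 2 && band[1] < band[2]) {
    c(lo = band[1], hi = band[2])
  } else {
    abort("`band` must be 'alpha', 'beta' or c(lo, hi).")
  }
}

#' Per-epoch ERD/S values
#'
#' Quantifies event-related (de)synchronization per kept epoch and channel:
#' the epoch is bandpass filtered (zero-phase FIR, same design as the
#' preprocessing filter), squared to a continuous band-power time course, and
#' power is averaged over the reference window R and the activation window A
#' (half-open windows in seconds relative to cue onset). The ERD/S value is
#' `100 * (A - R) / R`: negative values are desynchronization (activation),
#' positive values synchronization.
#'
#' @param epochs An [extract_epochs()] result (after rejection).
#' @param band `"alpha"`, `"beta"` or `c(lo, hi)` in Hz.
#' @param ref_window Reference window, default `c(-1.5, 0)` s.
#' @param act_window Activation window, default `c(2, 6)` s.
#' @param channels Optional subset of channel labels to process (default all).
#' @return Matrix kept-trials x channels of ERD/S percentages; rownames are
#'   the original trial indices. Cells with numerically zero reference power
#'   (below 1e-10 square-microvolts, far under any physical band power) are
#'   `NA` and listed in the `undefined_cells` attribute (a warning is
#'   raised).
#' @export
erds_per_epoch <- function(epochs, band, ref_window = c(-1.5, 0),
                           act_window = c(2, 6), channels = NULL) {
  bl <- band_limits(band)
  ch_sel <- channels %||% epochs$channel_labels
  if (!all(ch_sel %in% epochs$channel_labels)) {
    abort("`channels` must be a subset of the epoch channels.")
  }
  times <- epoch_times(epochs)
  if (ref_window[1] < epochs$tmin || act_window[2] > epochs$tmax) {
    abort("Analysis windows must lie inside the epoch window.")
  }
  ref_ix <- window_index(times, ref_window[1], ref_window[2])
  act_ix <- window_index(times, act_window[1], act_window[2])
  h <- design_fir_bandpass(bl["lo"], bl["hi"], epochs$fs)
  kept <- which(epochs$kept)
  ch_ix <- match(ch_sel, epochs$channel_labels)
  nch <- length(ch_ix)
  ns <- dim(epochs$data)[3]
  out <- matrix(NA_real_, nrow = length(kept), ncol = nch,
                dimnames = list(kept, ch_sel))
  # filter trials in blocks: rows are (trial, channel) pairs, trial fastest
  block <- max(1L, 512L %/% nch)   # bounds the FFT workspace
  for (b in split(seq_along(kept), (seq_along(kept) - 1L) %/% block)) {
    x <- matrix(epochs$data[kept[b], ch_ix, , drop = FALSE],
                nrow = length(b) * nch, ncol = ns)
    pw <- fft_filter_rows(x, h)^2
    A <- rowMeans(pw[, act_ix, drop = FALSE])
    R <- rowMeans(pw[, ref_ix, drop = FALSE])
    erds <- 100 * (A - R) / R
    erds[R < 1e-10] <- NA_real_
    out[b, ] <- matrix(erds, nrow = length(b), ncol = nch)
  }
  undef <- which(is.na(out), arr.ind = TRUE)
  if (nrow(undef) > 0) {
    warn(sprintf("%d cell(s) have zero reference power; ERD/S undefined (NA).",
                 nrow(undef)))
  }
  attr(out, "undefined_cells") <- undef
  attr(out, "band") <- if (is.character(band)) band else paste(bl, collapse = "-")
  out
}

#' Condition means of per-epoch ERD/S values
#'
#' Averages per-epoch ERD/S values over kept trials within each condition,
#' yielding channel-level rows of the tidy ERD/S table.
#'
#' @param per_epoch Matrix from [erds_per_epoch()] (kept trials x channels).
#' @param condition Character vector of per-trial condition labels, parallel
#'   to the rows of `per_epoch`.
#' @param meta Named list merged into every row (e.g. participant, group,
#'   sex, task, band).
#' @param expected_conditions If supplied, an error is raised for any
#'   expected condition with no kept trial (missing cell).
#' @return Tibble with columns from `meta` plus `condition`, `level`
#'   (channel label) and `erds_percent`.
#' @export
mean_erds_by_condition <- function(per_epoch, condition, meta = list(),
                                   expected_conditions = NULL) {
  if (length(condition) != nrow(per_epoch)) {
    abort("`condition` must have one label per row of `per_epoch`.")
  }
  if (!is.null(expected_conditions)) {
    missing <- setdiff(expected_conditions, unique(condition))
    if (length(missing)) {
      abort(sprintf("No kept trials for condition(s): %s",
                    paste(missing, collapse = ", ")))
    }
  }
  rows <- lapply(unique(condition), function(cond) {
    m <- colMeans(per_epoch[condition == cond, , drop = FALSE])
    tibble::tibble(!!!meta, condition = cond, level = names(m),
                   erds_percent = unname(m))
  })
  dplyr::bind_rows(rows)
}

#' ROI means of a channel-level ERD/S table
#'
#' Aggregates channel-level rows to region-of-interest rows by the unweighted
#' mean over each ROI's member channels, within every other grouping column.
#'
#' @param channel_table Tibble from [mean_erds_by_condition()] with `level`
#'   holding channel labels.
#' @param rois Named list of channel vectors, default [roi_set()].
#' @return Tibble of the same shape with `level` holding ROI names.
#' @export
roi_means <- function(channel_table, rois = roi_set()) {
  have <- unique(channel_table$level)
  for (nm in names(rois)) {
    missing <- setdiff(rois[[nm]], have)
    if (length(missing)) {
      abort(sprintf("ROI %s: channel(s) %s missing from channel-level table.",
                    nm, paste(missing, collapse = ", ")))
    }
  }
  membership <- tibble::tibble(
    level = unlist(rois, use.names = FALSE),
    roi = rep(names(rois), lengths(rois))
  )
  group_cols <- setdiff(names(channel_table), c("level", "erds_percent"))
  channel_table |>
    dplyr::inner_join(membership, by = "level") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_cols, "roi")))) |>
    dplyr::summarise(erds_percent = mean(.data$erds_percent), .groups = "drop") |>
    dplyr::rename(level = "roi")
}

#' Grand averages over participants
#'
#' Unweighted mean of per-participant ERD/S values over participants, within
#' group, task, band, condition and level.
#'
#' @param erds_table Tidy ERD/S table with a `participant` column.
#' @return Tibble grouped by `group`, `task`, `band`, `condition`, `level`
#'   with columns `erds_percent` (mean) and `n_participants`.
#' @export
grand_average_erds <- function(erds_table) {
  keys <- intersect(c("group", "task", "band", "condition", "level"),
                    names(erds_table))
  erds_table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_participants = dplyr::n_distinct(.data$participant),
                     erds_percent = mean(.data$erds_percent),
                     .groups = "drop")
}
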