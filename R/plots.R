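#' Topographic scatter of channel-level ERD/S values
#'
#' Plots channel-level ERD/S values at their 2-D projected electrode
#' positions (azimuthal equidistant projection of the spherical montage),
#' one panel per condition; red = desynchronization, blue =
#' synchronization.
#'
#' @param channel_table Channel-level ERD/S table (one participant/grand
#'   average, one task and band).
#' @param montage Montage tibble, default [standard_montage()].
#' @return A ggplot.
#' @export
plot_erds_topography <- function(channel_table, montage = standard_montage()) {
  proj <- montage |>
    dplyr::filter(.data$kind == "EEG") |>
    dplyr::mutate(r = .data$polar_deg / 90,
                  px = .data$r * sin(.data$azimuth_deg * pi / 180),
                  py = .data$r * cos(.data$azimuth_deg * pi / 180)) |>
    dplyr::select(level = "channel", "px", "py")
  df <- dplyr::inner_join(channel_table, proj, by = "level")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py,
                                   color = .data$erds_percent)) +
    ggplot2::geom_point(size = 5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$level), size = 2,
                       vjust = -1.5, color = "grey30") +
    ggplot2::scale_color_gradient2(low = "#b2182b", mid = "white",
                                   high = "#2166ac", midpoint = 0,
                                   name = "ERD/S (%)") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Profile plot of estimated marginal means
#'
#' @param object An [mixed_rm_anova()] result.
#' @param effect Effect whose marginal means to plot (default
#'   `"roi:handedness"`).
#' @return A ggplot with one line per trailing factor and ~95% confidence
#'   intervals (`emmean +- qt(.975, df) * se`).
#' @export
plot_emmeans <- function(object, effect = "roi:handedness") {
  em <- emmeans_erds(object, effect)
  facs <- strsplit(effect, ":", fixed = TRUE)[[1]]
  xvar <- facs[1]
  gvar <- if (length(facs) > 1) facs[2] else NULL
  em$lo <- em$emmean - stats::qt(0.975, em$df) * em$se
  em$hi <- em$emmean + stats::qt(0.975, em$df) * em$se
  aes <- if (is.null(gvar)) {
    ggplot2::aes(x = .data[[xvar]], y = .data$emmean, group = 1)
  } else {
    ggplot2::aes(x = .data[[xvar]], y = .data$emmean,
                 color = .data[[gvar]], group = .data[[gvar]])
  }
  ggplot2::ggplot(em, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::labs(y = "ERD/S (%)") +
    ggplot2::theme_minimal()
}
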