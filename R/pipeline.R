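#' Pipeline configuration
#'
#' Declarative configuration of a full simulate-preprocess-ERD/S-stats run.
#' Can be built in code or loaded from a YAML file ([read_pipeline_config()]).
#'
#' @param simulation A [simulation_config()].
#' @param n_left,n_right Cohort sizes per handedness group (defaults 14/14).
#' @param threshold_uV Peak-to-peak epoch rejection threshold (default 120).
#' @param corr_threshold EOG-correlation threshold for ICA component removal
#'   (default 0.7).
#' @param skip_ica Skip ocular-component removal.
#' @param bands Band definition tibble, default [band_defs()].
#' @param rois ROI list, default [roi_set()].
#' @param alpha Significance level reported by the ANOVAs (default 0.05).
#' @param seed Global seed; all stage seeds derive from it.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param erds_channels Optional channel subset for the ERD/S stage (default:
#'   all channels; restricting to the ROI channels speeds up large
#'   replication studies).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            n_left = 14, n_right = 14,
                            threshold_uV = 120, corr_threshold = 0.7,
                            skip_ica = FALSE, bands = band_defs(),
                            rois = roi_set(), alpha = 0.05, seed = 1,
                            out_dir = NULL, erds_channels = NULL) {
  validate_roi_set(rois, simulation$montage)
  structure(
    list(simulation = simulation, n_left = n_left, n_right = n_right,
         threshold_uV = threshold_uV, corr_threshold = corr_threshold,
         skip_ica = skip_ica, bands = bands, rois = rois, alpha = alpha,
         seed = seed, out_dir = out_dir, erds_channels = erds_channels),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Only keys present in the file override the defaults; nested `simulation`
#' keys override the simulation defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  sim <- do.call(simulation_config, sim_args)
  args <- y[setdiff(names(y), "simulation")]
  do.call(pipeline_config, c(list(simulation = sim), args))
}

#' Summarize epoch bookkeeping over a cohort
#'
#' Totals the rejection reports of every run into cohort-level epoch counts.
#' Accepts either a list of [reject_by_ptp()] reports or a data frame with
#' columns `n_total` and `n_rejected` (one row per run or per cohort).
#'
#' @param reports List of `rejection_report` objects, or a data frame of
#'   totals.
#' @param n_participants Number of participants (for the summary row).
#' @return One-row tibble of class `cohort_summary`: `n_participants`,
#'   `epochs_total`, `epochs_rejected`, `epochs_kept`, `kept_percent`
#'   (full precision; printed with 2 decimals).
#' @export
summarize_cohort <- function(reports, n_participants = NA_integer_) {
  if (is.data.frame(reports)) {
    total <- sum(reports$n_total)
    rejected <- sum(reports$n_rejected)
  } else {
    total <- sum(vapply(reports, function(r) attr(r, "n_total"), numeric(1)))
    rejected <- sum(vapply(reports, function(r) attr(r, "n_rejected"),
                           numeric(1)))
  }
  out <- tibble::tibble(
    n_participants = n_participants,
    epochs_total = total,
    epochs_rejected = rejected,
    epochs_kept = total - rejected,
    kept_percent = 100 * (total - rejected) / total
  )
  class(out) <- c("cohort_summary", class(out))
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "Cohort: %s participants, %d epochs, %d rejected, %d kept (%.2f%%)\n",
    ifelse(is.na(x$n_participants), "?", x$n_participants),
    x$epochs_total, x$epochs_rejected, x$epochs_kept, x$kept_percent))
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, preprocess, ERD/S and stats in order for a whole
#' cohort, one participant at a time (bounded memory). Produces the tidy
#' channel- and ROI-level ERD/S tables, grand averages, the cohort epoch
#' summary, and the four mixed RM-ANOVAs (task x band). All randomness is
#' derived from `config$seed`; re-running with the same configuration
#' reproduces every numeric table exactly. If `config$out_dir` is set, the
#' tables are written as CSV plus a JSON manifest of seeds, parameters,
#' rejected epochs and removed ICA components.
#'
#' @param config A [pipeline_config()].
#' @param progress Print per-participant progress messages.
#' @return List of class `erds_pipeline`: `manifest`, `erds_channel`,
#'   `erds_roi`, `grand_average`, `rejections`, `summary`, `anovas` (named
#'   list; entries are `erds_anova` objects or, when the design is invalid,
#'   the error condition), `config`.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  sim <- config$simulation
  manifest <- cohort_manifest(config$n_left, config$n_right, config$seed,
                              start_with = sim$start_with,
                              alternate = sim$alternate_start)
  rejections <- list()
  ica_removed <- list()
  channel_rows <- list()

  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    if (progress) inform(sprintf("participant %s (%s)", m$participant, m$group))
    sched <- build_schedule(sim$n_runs, sim$trials_per_condition,
                            sim$jitter_range, seed = derive_seed(m$seed, 0L),
                            start_with = m$start_with)
    part <- simulate_participant(sim, sched, m$seed,
                                 meta = list(participant = m$participant,
                                             group = m$group, sex = m$sex))
    # collect per-epoch ERD/S per task and band across runs
    per_task <- list()
    for (run in part$runs) {
      pp <- preprocess_raw(run, threshold_uV = config$threshold_uV,
                           corr_threshold = config$corr_threshold,
                           skip_ica = config$skip_ica)
      rejections[[length(rejections) + 1L]] <- pp$rejection
      ica_removed[[sprintf("%s_run%02d", m$participant, run$meta$run)]] <-
        if (is.null(pp$ica)) integer() else which(pp$ica$removed)
      task <- run$meta$task
      for (bi in seq_len(nrow(config$bands))) {
        band <- config$bands$band[bi]
        pe <- erds_per_epoch(pp$epochs, c(config$bands$lo[bi],
                                          config$bands$hi[bi]),
                             channels = config$erds_channels)
        key <- paste(task, band, sep = "_")
        kept_cond <- pp$epochs$info$condition[pp$epochs$kept]
        per_task[[key]] <- list(
          values = rbind(per_task[[key]]$values, pe),
          condition = c(per_task[[key]]$condition, kept_cond),
          task = task, band = band
        )
      }
    }
    for (entry in per_task) {
      channel_rows[[length(channel_rows) + 1L]] <- mean_erds_by_condition(
        entry$values, entry$condition,
        meta = list(participant = m$participant, group = m$group,
                    sex = m$sex, task = entry$task, band = entry$band),
        expected_conditions = c("LEFT", "RIGHT", "BOTH")
      )
    }
  }

  erds_channel <- dplyr::bind_rows(channel_rows)
  erds_roi <- roi_means(erds_channel, config$rois)
  grand <- grand_average_erds(erds_roi)
  summary <- summarize_cohort(
    tibble::tibble(
      n_total = vapply(rejections, function(r) attr(r, "n_total"), numeric(1)),
      n_rejected = vapply(rejections, function(r) attr(r, "n_rejected"),
                          numeric(1))),
    n_participants = nrow(manifest))
  anovas <- run_erds_anovas(erds_roi)

  result <- structure(
    list(manifest = manifest, erds_channel = erds_channel,
         erds_roi = erds_roi, grand_average = grand,
         rejections = rejections, summary = summary,
         anovas = anovas, ica_removed = ica_removed, config = config),
    class = "erds_pipeline"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' @export
print.erds_pipeline <- function(x, ...) {
  print(x$summary)
  ok <- vapply(x$anovas, inherits, logical(1), "erds_anova")
  cat(sprintf("ANOVAs: %s\n", paste(
    sprintf("%s[%s]", names(x$anovas), ifelse(ok, "ok", "error")),
    collapse = " ")))
  invisible(x)
}

# Write all pipeline tables + a JSON manifest into `dir`.
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wcsv(result$manifest, "manifest.csv")
  wcsv(result$erds_channel, "erds_channel.csv")
  wcsv(result$erds_roi, "erds_roi.csv")
  wcsv(result$grand_average, "grand_average.csv")
  rej <- dplyr::bind_rows(lapply(seq_along(result$rejections), function(i) {
    r <- result$rejections[[i]]
    tibble::tibble(record = i, n_total = attr(r, "n_total"),
                   n_rejected = attr(r, "n_rejected"),
                   threshold_uV = attr(r, "threshold_uV"))
  }))
  wcsv(rej, "rejection_summary.csv")
  wcsv(result$summary, "cohort_summary.csv")
  for (nm in names(result$anovas)) {
    a <- result$anovas[[nm]]
    if (inherits(a, "erds_anova")) {
      wcsv(tidy.erds_anova(a), sprintf("anova_%s.csv", nm))
    }
  }
  manifest <- list(
    seed = result$config$seed,
    participant_seeds = stats::setNames(as.list(result$manifest$seed),
                                        result$manifest$participant),
    threshold_uV = result$config$threshold_uV,
    corr_threshold = result$config$corr_threshold,
    skip_ica = result$config$skip_ica,
    ica_removed = result$ica_removed,
    anova_errors = lapply(result$anovas, function(a) {
      if (inherits(a, "erds_anova")) NULL else conditionMessage(a)
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
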