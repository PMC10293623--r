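# Shared fixtures: all built in code at test time.

eeg_labels <- function() {
  m <- standard_montage()
  m$channel[m$kind == "EEG"]
}

# Minimal raw recording with user-supplied data over the full montage.
make_raw <- function(data, fs = 500, events = NULL) {
  m <- standard_montage()
  stopifnot(nrow(data) == nrow(m))
  rownames(data) <- m$channel
  events <- events %||% tibble::tibble(sample = integer(), task = character(),
                                       condition = character())
  raw_recording(data, fs, m$kind, m, events)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Synthetic epochs object with given per-trial data (trials x channels x
# samples over the full montage).
make_epochs <- function(data, fs = 500, tmin = -2,
                        condition = rep("LEFT", dim(data)[1]),
                        task = "MI") {
  m <- standard_montage()
  stopifnot(dim(data)[2] == nrow(m))
  dimnames(data) <- list(NULL, m$channel, NULL)
  structure(
    list(data = data, fs = fs, tmin = tmin,
         tmax = tmin + dim(data)[3] / fs,
         info = tibble::tibble(trial = seq_len(dim(data)[1]), task = task,
                               condition = condition),
         kept = rep(TRUE, dim(data)[1]),
         channel_labels = m$channel, channel_kinds = m$kind, montage = m,
         meta = list()),
    class = "eeg_epochs"
  )
}

# Small fast simulation configuration used by several tests.
fast_sim_config <- function(trials_per_condition = 2, ...) {
  simulation_config(n_runs = 1, trials_per_condition = trials_per_condition,
                    blink_rate = 0, ...)
}

# Uniform ERD profile: one g applied to alpha on one hemisphere for every
# condition, task and group (makes every trial informative for recovery).
uniform_alpha_profile <- function(g, hemisphere = "left") {
  tidyr::expand_grid(group = c("lefthanded", "righthanded"),
                     task = c("ME", "MI"),
                     condition = c("LEFT", "RIGHT", "BOTH"),
                     band = "alpha", hemisphere = hemisphere, g = g)
}

# Pipeline-estimated mean ERD/S over the left-central channels for a
# participant simulated with scaling `g` on left-hemisphere alpha.
recover_erds <- function(g, n_runs = 2, trials_per_condition = 34, seed = 1) {
  cfg <- simulation_config(n_runs = n_runs,
                           trials_per_condition = trials_per_condition,
                           erd_profile = uniform_alpha_profile(g),
                           blink_rate = 0)
  sched <- build_schedule(n_runs, trials_per_condition, seed = seed)
  part <- simulate_participant(cfg, sched, derive_seed_for_test(seed))
  vals <- lapply(part$runs, function(run) {
    pp <- preprocess_raw(run, skip_ica = TRUE)
    erds_per_epoch(pp$epochs, "alpha", channels = roi_set()$CL)
  })
  v <- do.call(rbind, vals)
  list(mean = mean(rowMeans(v)), n_trials = nrow(v))
}

derive_seed_for_test <- function(seed) seed * 101L + 7L
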