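#' Simulation configuration
#'
#' Bundles every knob of the synthetic-EEG generator. The defaults reproduce
#' the study paradigm the package targets: 500 Hz sampling, 6 runs alternating
#' motor execution and motor imagery, 10 trials per condition per run, a
#' 32-channel 10-20 montage with two EOG channels, band-limited mu (8-13 Hz)
#' and beta (16-24 Hz) rhythms over sensorimotor/posterior channels, 1/f
#' background noise and frontal blink artifacts mirrored on the EOG channels.
#'
#' Ground-truth event-related power modulation is injected through
#' `erd_profile`: during the activation window of each matching trial the
#' rhythm amplitude is scaled by `sqrt(g)`, so mean band power is scaled by
#' `g` and the downstream ERD/S estimate has expectation `(g - 1) * 100` %.
#'
#' @param fs Sampling rate in Hz (default 500).
#' @param n_runs Number of runs per participant (default 6, alternating
#'   ME/MI).
#' @param trials_per_condition Trials per condition per run (default 10).
#' @param montage Montage tibble, see [standard_montage()].
#' @param noise_psd_exponent Spectral slope of the background noise
#'   (power ~ 1/f^exponent, default 1).
#' @param noise_rms RMS amplitude of the background noise per channel in
#'   microvolts (default 6).
#' @param rhythm_defs Tibble with columns `band`, `lo`, `hi`, `channel`,
#'   `amplitude_uV` (baseline RMS amplitude of that narrowband rhythm on that
#'   channel). See [default_rhythm_defs()].
#' @param erd_profile Tibble with columns `group`, `task`, `condition`,
#'   `band`, `hemisphere`, `g`: power scaling applied during the activation
#'   window. See [default_erd_profile()].
#' @param blink_rate Blink events per minute (default 8; 0 disables ocular
#'   artifacts).
#' @param blink_amplitude_uV Blink peak amplitude at the frontopolar channels
#'   in microvolts (default 90).
#' @param act_window Activation window in seconds relative to cue onset over
#'   which the power scaling applies (default `c(2, 6)`), entered/left with
#'   `ramp_s` cosine amplitude ramps lying outside the window.
#' @param ramp_s Ramp duration in seconds (default 0.25).
#' @param jitter_range Break jitter bounds in seconds (default `c(3, 5)`).
#' @param start_with Task of the first run, `"ME"` or `"MI"`.
#' @param alternate_start In cohort simulation, alternate the starting task
#'   across participants so roughly half begin with an MI run (default
#'   `TRUE`); with `FALSE` every participant starts with `start_with`.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(fs = 500, n_runs = 6, trials_per_condition = 10,
                              montage = standard_montage(),
                              noise_psd_exponent = 1, noise_rms = 6,
                              rhythm_defs = default_rhythm_defs(),
                              erd_profile = default_erd_profile(),
                              blink_rate = 8, blink_amplitude_uV = 90,
                              act_window = c(2, 6), ramp_s = 0.25,
                              jitter_range = c(3, 5),
                              start_with = c("ME", "MI"),
                              alternate_start = TRUE) {
  start_with <- match.arg(start_with)
  cfg <- list(fs = fs, n_runs = n_runs,
              trials_per_condition = trials_per_condition,
              montage = montage, noise_psd_exponent = noise_psd_exponent,
              noise_rms = noise_rms, rhythm_defs = rhythm_defs,
              erd_profile = erd_profile, blink_rate = blink_rate,
              blink_amplitude_uV = blink_amplitude_uV,
              act_window = act_window, ramp_s = ramp_s,
              jitter_range = jitter_range, start_with = start_with,
              alternate_start = alternate_start)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (any(cfg$erd_profile$g <= 0)) abort("All power scalings `g` must be > 0.")
  if (cfg$fs <= 2 * max(cfg$rhythm_defs$hi)) {
    abort("`fs` must exceed twice the highest rhythm frequency.")
  }
  bad <- setdiff(cfg$rhythm_defs$channel, cfg$montage$channel)
  if (length(bad)) {
    abort(sprintf("Rhythm channels absent from montage: %s",
                  paste(bad, collapse = ", ")))
  }
  prof_ch <- unique(unlist(lapply(unique(cfg$erd_profile$hemisphere),
                                  hemisphere_channels)))
  bad <- setdiff(prof_ch, cfg$montage$channel)
  if (length(bad)) {
    abort(sprintf("ERD-profile channels absent from montage: %s",
                  paste(bad, collapse = ", ")))
  }
  validate_roi_set(roi_set(), cfg$montage)
  cfg
}

#' Default baseline rhythm definitions
#'
#' Mu-band (8-13 Hz) rhythms over both central electrode groups and the
#' parieto-occipital channels, plus beta-band (16-24 Hz) rhythms over the
#' central groups, with baseline RMS amplitudes typical of scalp EEG.
#'
#' @return Tibble with columns `band`, `lo`, `hi`, `channel`, `amplitude_uV`.
#' @export
default_rhythm_defs <- function() {
  central <- c(roi_set()$CL, roi_set()$CR)
  posterior <- c("P3", "P4", "P7", "P8", "Pz", "O1", "O2", "Oz")
  dplyr::bind_rows(
    tibble::tibble(band = "alpha", lo = 8, hi = 13, channel = central,
                   amplitude_uV = 9),
    tibble::tibble(band = "alpha", lo = 8, hi = 13, channel = posterior,
                   amplitude_uV = 8),
    tibble::tibble(band = "beta", lo = 16, hi = 24, channel = central,
                   amplitude_uV = 5)
  )
}

#' Default ground-truth ERD profile
#'
#' Contralateral mu-band desynchronization during unimanual trials (power
#' scaling g = 0.6 over the central group opposite the moved hand), bilateral
#' mu desynchronization for bimanual trials (g = 0.65), and broader bilateral
#' beta desynchronization in all conditions (g = 0.75); identical for both
#' handedness groups and both tasks.
#'
#' @return Tibble with columns `group`, `task`, `condition`, `band`,
#'   `hemisphere`, `g`.
#' @export
default_erd_profile <- function() {
  base <- dplyr::bind_rows(
    tibble::tibble(condition = "RIGHT", band = "alpha", hemisphere = "left",  g = 0.6),
    tibble::tibble(condition = "LEFT",  band = "alpha", hemisphere = "right", g = 0.6),
    tibble::tibble(condition = "BOTH",  band = "alpha", hemisphere = c("left", "right"), g = 0.65),
    tidyr::expand_grid(condition = c("LEFT", "RIGHT", "BOTH"), band = "beta",
                       hemisphere = c("left", "right"), g = 0.75)
  )
  tidyr::expand_grid(group = c("lefthanded", "righthanded"),
                     task = c("ME", "MI")) |>
    dplyr::cross_join(base)
}

# --- signal primitives ------------------------------------------------------

# 1/f^exponent background noise, FFT-shaped white Gaussian noise normalized
# to `rms` microvolts per channel. The amplitude profile is clipped below
# 1 Hz so the spectrum does not diverge at DC. Generated for all channels at
# once at a power-of-two length and truncated, keeping the FFT fast.
pink_noise <- function(n, exponent, fs, rms, n_channels = 1L) {
  m <- stats::nextn(n, c(2L, 3L, 5L))
  # complex white noise carries two channels per column (real/imaginary
  # parts stay independent under the real spectral shaping)
  npair <- ceiling(n_channels / 2)
  white <- matrix(complex(real = rnorm(m * npair),
                          imaginary = rnorm(m * npair)), m, npair)
  f <- seq(0, m - 1) * fs / m
  f <- pmin(f, fs - f)             # two-sided frequency magnitude
  amp <- pmax(f, 1)^(-exponent / 2)
  amp[1] <- 0                      # remove DC
  y <- mvfft(mvfft(white) * amp, inverse = TRUE)[seq_len(n), , drop = FALSE] / m
  x <- matrix(0, n_channels, n)
  x[seq(1L, n_channels, by = 2L), ] <- t(Re(y))
  if (n_channels > 1L) {
    x[seq(2L, n_channels, by = 2L), ] <- t(Im(y))[seq_len(n_channels %/% 2), , drop = FALSE]
  }
  sds <- sqrt(rowMeans(x^2) - rowMeans(x)^2)
  x * (rms / sds)                  # channels x samples
}

# Band-limited Gaussian noise with unit RMS.
band_noise <- function(n, lo, hi, fs) {
  h <- design_fir_bandpass(lo, hi, fs)
  x <- fft_filter_rows(rnorm(n), h)
  x / sd(x)
}

# Narrowband rhythm with (near-)constant modulus and unit RMS: a
# frequency-modulated oscillator whose instantaneous frequency wanders
# smoothly inside [lo, hi] (Ornstein-Uhlenbeck drive, soft-clipped), with a
# random initial phase. The constant envelope makes the band power averaged
# over any analysis window essentially deterministic, so the per-epoch
# power-ratio estimator recovers an injected scaling g without the upward
# bias (~ 1/(bandwidth x window length)) that a Gaussian-envelope rhythm
# would add through reference-power fluctuations.
rhythm_wave <- function(n, lo, hi, fs) {
  # frequency drift generated at 50 Hz and upsampled: it is smooth by
  # construction, so the decimation is lossless in practice
  dec <- max(1L, floor(fs / 50))
  nd <- ceiling(n / dec) + 1L
  rho <- exp(-1 / (0.2 * fs / dec))   # ~200 ms frequency coherence time
  z <- as.numeric(stats::filter(rnorm(nd) * sqrt(1 - rho^2), rho,
                                method = "recursive"))
  z <- stats::approx(seq_len(nd), z, xout = 1 + (seq_len(n) - 1) / dec)$y
  fc <- (lo + hi) / 2
  f_inst <- fc + (hi - lo) / 2 * 0.7 * tanh(z)
  phase <- 2 * pi * (cumsum(f_inst) / fs + runif(1))
  sqrt(2) * cos(phase)
}

# 300 ms biphasic blink template, peak-normalized to 1.
blink_template <- function(fs) {
  t <- seq(0, 0.3, by = 1 / fs)
  w <- exp(-((t - 0.1) / 0.045)^2) - 0.3 * exp(-((t - 0.215) / 0.06)^2)
  w / max(w)
}

# Spatial blink weights: exponential decay with great-circle distance from a
# point between the eyes, normalized so the frontopolar maximum is 1. EOG
# channels sit closest to the eyes and get the largest weights, which is what
# lets EOG-correlation-based component removal recover the artifact.
blink_weights <- function(montage) {
  eye <- c(x = 0, y = sin(105 * pi / 180), z = cos(105 * pi / 180))
  pos <- as.matrix(montage[, c("x", "y", "z")])
  d <- acos(pmin(1, pmax(-1, pos %*% eye)))
  w <- exp(-2.5 * drop(d))
  scalp_max <- max(w[montage$kind == "EEG"])
  setNames(w / scalp_max, montage$channel)
}

# Per-sample amplitude envelope for one (band, channel) in one run:
# 1 at baseline, sqrt(g) inside the activation window of matching trials,
# with cosine ramps of `ramp_s` seconds immediately before/after the window.
modulation_envelope <- function(n, fs, cue_samples, g_per_trial, act_window,
                                ramp_s) {
  env <- rep(1, n)
  n_ramp <- round(ramp_s * fs)
  u <- (1 - cos(pi * seq_len(n_ramp) / n_ramp)) / 2  # 0 -> 1
  for (k in seq_along(cue_samples)) {
    g <- g_per_trial[k]
    if (g == 1) next
    a <- sqrt(g)
    s0 <- cue_samples[k] + round(act_window[1] * fs)
    s1 <- cue_samples[k] + round(act_window[2] * fs) - 1L
    rise <- (s0 - n_ramp):(s0 - 1L)
    fall <- (s1 + 1L):(s1 + n_ramp)
    ok <- function(ix) ix[ix >= 1L & ix <= n]
    env[ok(rise)] <- 1 + (a - 1) * u[ok(rise) - (s0 - n_ramp) + 1L]
    env[ok(s0:s1)] <- a
    env[ok(fall)] <- a + (1 - a) * u[ok(fall) - s1]
  }
  env
}

# --- generation -------------------------------------------------------------

# Simulate one run as a raw_recording.
simulate_run <- function(config, sched_run, seed, meta) {
  fs <- config$fs
  dur <- max(sched_run$cue_onset_s) + (attr(sched_run, "cue_s") %||% 7) +
    max(sched_run$break_s)
  n <- ceiling((dur + 1) * fs)
  mont <- config$montage
  nch <- nrow(mont)
  cue_samples <- round(sched_run$cue_onset_s * fs) + 1L
  task <- sched_run$task[1]

  # per-trial power scaling per (band, hemisphere)
  prof <- config$erd_profile
  prof <- prof[prof$task == task &
                 prof$group == (meta$group %||% prof$group[1]), ]
  g_lookup <- function(band, channel) {
    g <- rep(1, nrow(sched_run))
    hit <- prof[prof$band == band, ]
    for (i in seq_len(nrow(hit))) {
      if (channel %in% hemisphere_channels(hit$hemisphere[i])) {
        g[sched_run$condition == hit$condition[i]] <- hit$g[i]
      }
    }
    g
  }

  with_seed(seed, {
    data <- pink_noise(n, config$noise_psd_exponent, fs, config$noise_rms,
                       n_channels = nch)
    dimnames(data) <- list(mont$channel, NULL)
    defs <- config$rhythm_defs
    for (ri in seq_len(nrow(defs))) {
      ch <- defs$channel[ri]
      x <- rhythm_wave(n, defs$lo[ri], defs$hi[ri], fs) * defs$amplitude_uV[ri]
      env <- modulation_envelope(n, fs, cue_samples,
                                 g_lookup(defs$band[ri], ch),
                                 config$act_window, config$ramp_s)
      data[ch, ] <- data[ch, ] + x * env
    }
    if (config$blink_rate > 0) {
      n_blinks <- rpois(1, config$blink_rate * n / fs / 60)
      if (n_blinks > 0) {
        tmpl <- blink_template(fs)
        s <- rep(0, n)
        starts <- sort(sample.int(n - length(tmpl), n_blinks))
        for (b in starts) {
          ix <- b:(b + length(tmpl) - 1L)
          s[ix] <- s[ix] + tmpl
        }
        w <- blink_weights(mont)
        data <- data + (w[mont$channel] * config$blink_amplitude_uV) %o% s
      }
    }
    events <- tibble::tibble(sample = cue_samples, task = task,
                             condition = sched_run$condition)
    raw_recording(data, fs, mont$kind, mont, events,
                  meta = c(meta, list(run = sched_run$run[1], task = task,
                                      seed = seed)))
  })
}

#' Simulate one participant
#'
#' Generates all runs of one participant according to a trial schedule, with
#' ground-truth band-power modulation taken from the configuration's
#' `erd_profile`. Each rhythm is band-limited Gaussian noise whose amplitude
#' is scaled by `sqrt(g)` during the activation window of matching trials, so
#' that mean band power during the activation window equals `g` times mean
#' baseline band power in expectation. 1/f background noise and (optionally)
#' frontal blink transients mirrored on the EOG channels are superimposed.
#' Fully reproducible: the output is a pure function of the configuration,
#' the schedule and `participant_seed`.
#'
#' @param config A [simulation_config()].
#' @param schedule A [build_schedule()] result.
#' @param participant_seed Integer seed for this participant.
#' @param meta Named list: `participant`, `group` ("lefthanded"/
#'   "righthanded"), `sex` ("female"/"male").
#' @return An object of class `participant_recording`: list with `runs`
#'   (list of [raw_recording()], one per run), `meta` and `schedule`.
#' @export
simulate_participant <- function(config, schedule, participant_seed,
                                 meta = list(participant = "P001",
                                             group = "righthanded",
                                             sex = "female")) {
  if (nrow(schedule) == 0) abort("`schedule` must contain at least one trial.")
  runs <- lapply(unique(schedule$run), function(r) {
    simulate_run(config, schedule[schedule$run == r, ],
                 derive_seed(participant_seed, r), meta)
  })
  structure(list(runs = runs, meta = meta, schedule = schedule),
            class = "participant_recording")
}

#' @export
print.participant_recording <- function(x, ...) {
  cat(sprintf("<participant_recording> %s (%s, %s): %d runs, %d trials\n",
              x$meta$participant %||% "?", x$meta$group %||% "?",
              x$meta$sex %||% "?", length(x$runs), nrow(x$schedule)))
  invisible(x)
}

#' Simulate a cohort of participants
#'
#' Derives per-participant seeds deterministically from `cohort_seed`,
#' assigns handedness groups of the requested sizes with sex alternating
#' within each group (balanced design) and the starting task alternating
#' across participants, and simulates every participant.
#'
#' @param config A [simulation_config()].
#' @param n_left,n_right Number of left-/right-handed participants.
#' @param cohort_seed Integer seed for the whole cohort.
#' @return List with `recordings` (list of `participant_recording`) and
#'   `manifest` (tibble: participant, group, sex, start_with, seed).
#' @export
simulate_cohort <- function(config, n_left = 14, n_right = 14,
                            cohort_seed = 1) {
  if (n_left < 0 || n_right < 0) abort("Group sizes must be non-negative.")
  manifest <- cohort_manifest(n_left, n_right, cohort_seed,
                              start_with = config$start_with,
                              alternate = config$alternate_start)
  recordings <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    sched <- build_schedule(config$n_runs, config$trials_per_condition,
                            config$jitter_range,
                            seed = derive_seed(m$seed, 0L),
                            start_with = m$start_with)
    simulate_participant(config, sched, m$seed,
                         meta = list(participant = m$participant,
                                     group = m$group, sex = m$sex))
  })
  list(recordings = recordings, manifest = manifest)
}

# Deterministic cohort bookkeeping (shared with run_pipeline, which simulates
# participants one at a time to bound memory).
cohort_manifest <- function(n_left, n_right, cohort_seed,
                            start_with = "ME", alternate = TRUE) {
  n <- n_left + n_right
  group <- c(rep("lefthanded", n_left), rep("righthanded", n_right))
  sex <- unlist(lapply(c(n_left, n_right), function(k) {
    rep(c("female", "male"), length.out = k)
  }))
  starts <- if (alternate) {
    rep(c(start_with, setdiff(c("ME", "MI"), start_with)), length.out = n)
  } else {
    rep(start_with, n)
  }
  tibble::tibble(
    participant = sprintf("P%03d", seq_len(n)),
    group = group,
    sex = sex,
    start_with = starts,
    seed = vapply(seq_len(n), function(i) derive_seed(cohort_seed, i),
                  integer(1))
  )
}
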