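#' Build a randomized trial schedule
#'
#' Generates the paradigm's trial timeline: each run starts with a short
#' pre-run period, followed by trials consisting of a 2 s fixation cross,
#' a 7 s cue (the condition period) and a jittered 3-5 s break. Every run
#' contains exactly `trials_per_condition` trials of each of the three
#' conditions (LEFT, RIGHT, BOTH) in randomized order; runs alternate between
#' motor execution (ME) and motor imagery (MI).
#'
#' @param n_runs Number of runs (default 6, alternating ME/MI).
#' @param trials_per_condition Trials of each condition per run (default 10,
#'   i.e. 30 trials per run).
#' @param jitter_range Length-2 numeric, inclusive bounds in seconds of the
#'   uniformly jittered post-trial break (default `c(3, 5)`).
#' @param seed Integer seed; the condition permutation and the jitters are a
#'   pure function of it.
#' @param start_with First run's task, `"ME"` or `"MI"`; runs alternate from
#'   there.
#' @param fixation_s Fixation-cross duration before each cue (default 2 s).
#' @param cue_s Cue duration (default 7 s).
#' @param pre_run_s Instruction/blank period at the start of each run before
#'   the first trial (default 5 s).
#' @return A tibble of class `trial_schedule` with one row per trial:
#'   `run`, `trial`, `task`, `condition`, `cue_onset_s` (seconds from run
#'   start), `break_s`, plus the timing constants as attributes.
#' @export
#' @examples
#' sched <- build_schedule(6, 10, seed = 1)
#' nrow(sched)          # 180 trials per participant
#' table(sched$condition)
build_schedule <- function(n_runs = 6, trials_per_condition = 10,
                           jitter_range = c(3, 5), seed = 1,
                           start_with = c("ME", "MI"),
                           fixation_s = 2, cue_s = 7, pre_run_s = 5) {
  start_with <- match.arg(start_with)
  if (n_runs < 1 || trials_per_condition < 1) {
    abort("`n_runs` and `trials_per_condition` must be positive integers.")
  }
  if (length(jitter_range) != 2L || !all(is.finite(jitter_range)) ||
      jitter_range[1] > jitter_range[2] || jitter_range[1] < 0) {
    abort("`jitter_range` must be a valid non-negative interval c(lo, hi).")
  }
  conditions <- c("LEFT", "RIGHT", "BOTH")
  tasks <- rep(c(start_with, setdiff(c("ME", "MI"), start_with)),
               length.out = n_runs)
  runs <- with_seed(seed, lapply(seq_len(n_runs), function(r) {
    cond <- sample(rep(conditions, trials_per_condition))
    brk <- runif(length(cond), jitter_range[1], jitter_range[2])
    onset <- pre_run_s + fixation_s +
      cumsum(c(0, (fixation_s + cue_s + brk)[-length(cond)]))
    tibble::tibble(
      run = r, trial = seq_along(cond), task = tasks[r], condition = cond,
      cue_onset_s = onset, break_s = brk
    )
  }))
  out <- dplyr::bind_rows(runs)
  attr(out, "fixation_s") <- fixation_s
  attr(out, "cue_s") <- cue_s
  attr(out, "pre_run_s") <- pre_run_s
  attr(out, "jitter_range") <- jitter_range
  class(out) <- c("trial_schedule", class(out))
  out
}

# Duration in seconds of one run of a schedule (through the last break).
run_duration_s <- function(schedule, run) {
  rows <- schedule[schedule$run == run, ]
  cue_s <- attr(schedule, "cue_s") %||% 7
  last <- rows[which.max(rows$cue_onset_s), ]
  last$cue_onset_s + cue_s + last$break_s
}
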