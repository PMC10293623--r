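test_that("default schedule reproduces the study's trial arithmetic", {
  sched <- build_schedule(6, 10, seed = 1)
  expect_equal(nrow(sched), 180)
  per_run <- table(sched$run)
  expect_true(all(per_run == 30))
  # a 28-participant cohort yields 5040 epochs in total
  expect_equal(28 * nrow(sched), 5040)
})

test_that("every run is condition-balanced with valid timing, across seeds", {
  for (seed in 1:20) {
    sched <- build_schedule(3, 4, seed = seed)
    counts <- table(sched$run, sched$condition)
    expect_true(all(counts == 4))
    for (r in unique(sched$run)) {
      on <- sched$cue_onset_s[sched$run == r]
      expect_true(all(diff(on) > 0))
    }
    expect_true(all(sched$break_s >= 3 & sched$break_s <= 5))
    # trial spacing = fixation + cue + previous break
    gaps <- diff(sched$cue_onset_s[sched$run == 1])
    brk <- sched$break_s[sched$run == 1]
    expect_equal(gaps, 2 + 7 + utils::head(brk, -1), tolerance = 1e-12)
  }
})

test_that("minimal schedule has one trial per condition", {
  sched <- build_schedule(1, 1, seed = 0)
  expect_equal(nrow(sched), 3)
  expect_setequal(sched$condition, c("LEFT", "RIGHT", "BOTH"))
})

test_that("schedules are a pure function of the seed", {
  a <- build_schedule(2, 5, seed = 11)
  b <- build_schedule(2, 5, seed = 11)
  expect_identical(a, b)
  perms <- vapply(1:30, function(s) {
    paste(build_schedule(1, 3, seed = s)$condition, collapse = "")
  }, character(1))
  expect_gt(length(unique(perms)), 1)
})

test_that("tasks alternate from the requested starting task", {
  sched <- build_schedule(4, 1, seed = 1, start_with = "MI")
  expect_equal(sched$task[c(1, 4, 7, 10)], c("MI", "ME", "MI", "ME"))
})

test_that("invalid schedule arguments are rejected", {
  expect_error(build_schedule(0, 10, seed = 1), "positive")
  expect_error(build_schedule(6, 0, seed = 1), "positive")
  expect_error(build_schedule(1, 1, jitter_range = c(5, 3), seed = 1),
               "interval")
})
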