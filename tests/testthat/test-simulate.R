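test_that("simulation is a pure function of config and seeds", {
  cfg <- fast_sim_config()
  sched <- build_schedule(1, 2, seed = 3)
  a <- simulate_participant(cfg, sched, 77)
  b <- simulate_participant(cfg, sched, 77)
  expect_identical(a$runs[[1]]$data, b$runs[[1]]$data)
  c <- simulate_participant(cfg, sched, 78)
  expect_false(identical(a$runs[[1]]$data, c$runs[[1]]$data))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(erd_profile = dplyr::mutate(
    default_erd_profile(), g = 0)), "g")
  expect_error(simulation_config(fs = 40), "fs")
  bad_defs <- dplyr::add_row(default_rhythm_defs(), band = "alpha", lo = 8,
                             hi = 13, channel = "NOPE", amplitude_uV = 5)
  expect_error(simulation_config(rhythm_defs = bad_defs), "NOPE")
})

test_that("blink artifacts couple frontal and EOG channels; off-switch works", {
  sched <- build_schedule(1, 2, seed = 9)
  with_blinks <- simulate_participant(
    simulation_config(n_runs = 1, trials_per_condition = 2, blink_rate = 15),
    sched, 5)$runs[[1]]
  r_on <- abs(cor(with_blinks$data["Fp1", ], with_blinks$data["EOGV", ]))
  expect_gt(r_on, 0.3)
  no_blinks <- simulate_participant(fast_sim_config(), sched, 5)$runs[[1]]
  r_off <- abs(cor(no_blinks$data["Fp1", ], no_blinks$data["EOGV", ]))
  expect_lt(r_off, 0.1)
})

test_that("injected power scaling modulates activation-window band power", {
  g <- 0.5
  cfg <- simulation_config(n_runs = 1, trials_per_condition = 4,
                           erd_profile = uniform_alpha_profile(g),
                           blink_rate = 0, noise_rms = 0.5)
  sched <- build_schedule(1, 4, seed = 21)
  run <- simulate_participant(cfg, sched, 31)$runs[[1]]
  h <- erdspipe:::design_fir_bandpass(8, 13, run$fs)
  x2 <- erdspipe:::fft_filter_rows(run$data["C3", ], h)^2
  cue <- run$events$sample
  act <- unlist(lapply(cue, function(s) (s + 2 * run$fs):(s + 6 * run$fs - 1)))
  ref <- unlist(lapply(cue, function(s) (s - 1.5 * run$fs):(s - 1)))
  expect_equal(mean(x2[act]) / mean(x2[ref]), g, tolerance = 0.12)
  # un-modulated hemisphere stays at baseline power
  y2 <- erdspipe:::fft_filter_rows(run$data["C4", ], h)^2
  expect_equal(mean(y2[act]) / mean(y2[ref]), 1, tolerance = 0.12)
})

test_that("cohort manifest is balanced and deterministic", {
  co <- simulate_cohort(fast_sim_config(), n_left = 2, n_right = 2,
                        cohort_seed = 4)
  expect_length(co$recordings, 4)
  expect_equal(as.integer(table(co$manifest$group)), c(2L, 2L))
  expect_equal(sort(unique(co$manifest$sex)), c("female", "male"))
  m2 <- erdspipe:::cohort_manifest(2, 2, 4)
  expect_identical(co$manifest$seed, m2$seed)
  single <- simulate_cohort(fast_sim_config(), 0, 1, cohort_seed = 1)
  expect_length(single$recordings, 1)
})

test_that("identical cohort seeds give byte-identical exported files", {
  cfg <- simulation_config(n_runs = 1, trials_per_condition = 1,
                           blink_rate = 0)
  for (d in c("a", "b")) {
    co <- simulate_cohort(cfg, 0, 1, cohort_seed = 12)
    export_participant(co$recordings[[1]], file.path(tempdir(), "coh", d))
  }
  fa <- list.files(file.path(tempdir(), "coh", "a"), full.names = TRUE)
  fb <- list.files(file.path(tempdir(), "coh", "b"), full.names = TRUE)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
  unlink(file.path(tempdir(), "coh"), recursive = TRUE)
})
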