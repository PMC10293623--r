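test_that("the Tukey window matches the reference spectral window", {
  # frozen oracle values (periodic 250-point Tukey(0.25) and symmetric
  # 16-point variant) from an independent reference implementation
  w <- tukey_window(250, 0.25, periodic = TRUE)
  expect_equal(w[c(1, 6, 11, 16, 17, 32, 125, 219, 235, 241, 246, 250)],
               c(0, 0.061846659978, 0.232086602511, 0.468604740235,
                 0.518845091335, 0.999842094642, 1, 1,
                 0.518845091335, 0.232086602511, 0.061846659978,
                 0.002524491509),
               tolerance = 1e-10)
  ws <- tukey_window(16, 0.25)
  expect_equal(ws[c(1, 2, 3, 15, 16)],
               c(0, 0.552264231634, 1, 0.552264231634, 0), tolerance = 1e-10)
})

test_that("the spectrogram matches frozen reference oracle values", {
  fs <- 500
  n <- 0:999
  x <- sin(2 * pi * 10 * n / fs) + 0.5 * sin(2 * pi * 22 * n / fs + 0.3) +
    0.2 * cos(2 * pi * 3 * n / fs)
  w <- tukey_window(250, 0.25, periodic = TRUE)
  sp <- erdspipe:::stft_power(x, fs, 250, 225, w)
  expect_equal(sp$freqs[1:6], c(0, 2, 4, 6, 8, 10))
  expect_equal(sp$times[1:4], c(0.25, 0.30, 0.35, 0.40))
  expect_equal(dim(sp$power), c(126, 31))
  expect_equal(sp$power[6, 1:5],
               c(0.4837501446, 0.5046196082, 0.4968164584, 0.4883783718,
                 0.5091610678), tolerance = 1e-9)
  expect_equal(sp$power[12, 1:5],
               c(0.1132358292, 0.1320076654, 0.1245880437, 0.1178676359,
                 0.1364546903), tolerance = 1e-9)
  expect_equal(sp$power[3, 1:3],
               c(0.0017207453, 0.0210126038, 0.0165992951), tolerance = 1e-6)
})

test_that("map geometry follows segment length and overlap", {
  cfg <- fast_sim_config()
  sched <- build_schedule(1, 2, seed = 14)
  run <- simulate_participant(cfg, sched, 44)$runs[[1]]
  pp <- preprocess_raw(run, skip_ica = TRUE)
  tf <- tf_erds(pp$epochs, "CL")
  expect_equal(diff(tf$freqs)[1], 2)           # fs / segment_length
  expect_equal(diff(tf$times)[1], 0.05)        # (segment - overlap) / fs
  expect_equal(range(tf$freqs), c(2, 34))      # rows within [1, 35] Hz
  expect_equal(tf$times[1], -1.25)             # first full segment centre
  expect_error(tf_erds(pp$epochs, "CL", trange = c(-3, 7)), "inside")
  expect_error(tf_erds(pp$epochs, "CL", segment_length = 1e5), "exceeds")
  expect_error(tf_erds(pp$epochs, "NOPE"), "not in epochs")
})

test_that("alpha suppression appears in the map and agrees with the
           window-based estimate", {
  g <- 0.5
  cfg <- simulation_config(n_runs = 2, trials_per_condition = 4,
                           erd_profile = uniform_alpha_profile(g),
                           blink_rate = 0)
  sched <- build_schedule(2, 4, seed = 15)
  part <- simulate_participant(cfg, sched, 55)
  eps <- lapply(part$runs, function(r) {
    preprocess_raw(r, skip_ica = TRUE)$epochs
  })
  tf <- tf_erds(pool_epochs(eps), "CL")
  map_alpha <- tf_band_mean(tf, "alpha", c(2, 6))
  expect_lt(map_alpha, -30)
  expect_gt(map_alpha, -60)
  pe <- do.call(rbind, lapply(eps, erds_per_epoch, band = "alpha",
                              channels = roi_set()$CL))
  win_alpha <- mean(pe)
  expect_lt(abs(map_alpha - win_alpha), 15)
  expect_equal(sign(map_alpha), sign(win_alpha))
})
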