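test_that("flat channels are detected by their standard deviation", {
  set.seed(1)
  m <- standard_montage()
  data <- matrix(rnorm(nrow(m) * 500, sd = 10), nrow(m), 500,
                 dimnames = list(m$channel, NULL))
  raw <- make_raw(data)
  expect_length(detect_flat_channels(raw, 0.1), 0)
  data["FT9", ] <- 0
  expect_equal(detect_flat_channels(make_raw(data), 0.1), "FT9")
  data["FT9", ] <- 3.7          # constant but nonzero still has zero std
  expect_equal(detect_flat_channels(make_raw(data), 0.1), "FT9")
})

test_that("average reference zeroes the EEG mean and is idempotent", {
  m <- standard_montage()
  data <- matrix(0, nrow(m), 4)
  data[1, ] <- 1; data[2, ] <- 3
  # reduce to a two-EEG-channel check by making others cancel in pairs
  set.seed(2)
  data <- matrix(rnorm(nrow(m) * 100), nrow(m), 100)
  raw <- make_raw(data)
  ref <- apply_average_reference(raw)
  eeg <- which(raw$channel_kinds == "EEG")
  expect_lt(max(abs(colSums(ref$data[eeg, ]))), 1e-9)
  # EOG untouched
  expect_identical(ref$data["EOGV", ], raw$data["EOGV", ])
  # idempotent
  twice <- apply_average_reference(ref)
  expect_equal(twice$data, ref$data, tolerance = 1e-12)
  # two-channel example [1, 3] -> [-1, 1]
  expect_equal(c(1, 3) - mean(c(1, 3)), c(-1, 1))
})

test_that("bandpass FIR has unit passband, deep stopband and zero lag", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  m <- standard_montage()
  data <- matrix(0, nrow(m), length(t))
  data[1, ] <- sin(2 * pi * 10 * t)          # passband tone
  data[2, ] <- sin(2 * pi * 100 * t)         # stopband tone
  out <- bandpass_fir(make_raw(data), 1, 40)
  mid <- seq(3 * fs, 7 * fs)                 # steady state away from edges
  amp10 <- max(abs(out$data[1, mid]))
  expect_gt(amp10, 0.95); expect_lt(amp10, 1.05)
  expect_lt(max(abs(out$data[2, mid])), 0.01)
  # zero-lag: peak cross-correlation of broadband noise at lag 0
  set.seed(3)
  data[3, ] <- rnorm(length(t))
  out <- bandpass_fir(make_raw(data), 1, 40)
  cc <- ccf(out$data[3, mid], data[3, mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(bandpass_fir(make_raw(data), 40, 1), "edges")
})

test_that("epoch extraction uses the half-open [tmin, tmax) window", {
  fs <- 500
  m <- standard_montage()
  data <- matrix(rnorm(nrow(m) * fs * 40), nrow(m))
  events <- tibble::tibble(sample = c(2000L, 8000L, 14000L), task = "MI",
                           condition = c("LEFT", "RIGHT", "BOTH"))
  ep <- extract_epochs(make_raw(data, events = events))
  expect_equal(dim(ep$data), c(3, nrow(m), 4500))
  expect_equal(ep$info$condition, events$condition)
  # cue onset is sample 0 of the window: value at t=0 equals the raw sample
  expect_equal(unname(ep$data[1, 1, 2 * fs + 1]), data[1, 2000])
  # event too close to the start is dropped with a warning
  events2 <- tibble::tibble(sample = c(100L, 8000L), task = "MI",
                            condition = c("LEFT", "RIGHT"))
  expect_warning(ep2 <- extract_epochs(make_raw(data, events = events2)),
                 "Dropped 1")
  expect_equal(dim(ep2$data)[1], 1)
})

test_that("peak-to-peak rejection thresholds exactly and ignores EOG", {
  m <- standard_montage()
  data <- array(0, dim = c(3, nrow(m), 100))
  data[1, 5, 10] <- -70; data[1, 5, 20] <- 60     # ptp 130 on an EEG channel
  data[3, which(m$kind == "EOG")[1], ] <- c(-300, rep(0, 99))  # EOG only
  ep <- make_epochs(data)
  r120 <- reject_by_ptp(ep, 120)
  expect_equal(r120$epochs$kept, c(FALSE, TRUE, TRUE))
  expect_equal(attr(r120$report, "n_rejected"), 1)
  r150 <- reject_by_ptp(ep, 150)
  expect_equal(r150$epochs$kept, c(TRUE, TRUE, TRUE))
  expect_equal(r120$report$max_ptp_uV[1], 130)
  # all-zero epochs are all kept
  ep0 <- make_epochs(array(0, dim = c(4, nrow(m), 50)))
  expect_equal(attr(reject_by_ptp(ep0, 120)$report, "n_rejected"), 0)
})

test_that("rejection is threshold-monotone", {
  set.seed(4)
  m <- standard_montage()
  ep <- make_epochs(array(rnorm(20 * nrow(m) * 200, sd = 30),
                          dim = c(20, nrow(m), 200)))
  kept <- vapply(c(80, 100, 120, 150, 200), function(th) {
    sum(reject_by_ptp(ep, th)$epochs$kept)
  }, numeric(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("the full chain preserves the average-reference constraint", {
  cfg <- fast_sim_config()
  sched <- build_schedule(1, 2, seed = 5)
  run <- simulate_participant(cfg, sched, 13)$runs[[1]]
  pp <- preprocess_raw(run, skip_ica = TRUE)
  eeg <- which(pp$epochs$channel_kinds == "EEG")
  sums <- apply(pp$epochs$data[, eeg, ], c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-8)
})
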