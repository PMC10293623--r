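test_that("interpolation weights match a dense Perrin-series oracle", {
  mont <- standard_montage()
  eeg <- eeg_labels()
  bad <- c("FT9", "Cz")
  good <- setdiff(eeg, bad)
  W <- spline_interpolation_weights(mont, good, bad)
  W_oracle <- oracle_weights(mont, good, bad)
  expect_lt(max(abs(W - unname(W_oracle))), 1e-6)
})

test_that("splines reproduce constant fields exactly", {
  eeg <- eeg_labels()
  m <- standard_montage()
  data <- matrix(3.25, nrow(m), 50)
  raw <- make_raw(data)
  out <- interpolate_spherical_spline(raw, c("FT9", "P3"))
  expect_lt(max(abs(out$data[c("FT9", "P3"), ] - 3.25)) / 3.25, 1e-6)
})

test_that("a smooth first-order harmonic field is recovered", {
  m <- standard_montage()
  eeg <- eeg_labels()
  pos <- as.matrix(m[match(eeg, m$channel), c("x", "y", "z")])
  field <- 2 * pos[, 3] + pos[, 2]          # linear (degree-1) field
  data <- matrix(0, nrow(m), 20)
  data[match(eeg, m$channel), ] <- field
  out <- interpolate_spherical_spline(make_raw(data), "C3")
  truth <- field[eeg == "C3"]
  rel <- sqrt(mean((out$data["C3", ] - truth)^2)) / sd(field)
  expect_lt(rel, 0.1)
})

test_that("weights depend only on geometry and good channels are untouched", {
  m <- standard_montage()
  set.seed(6)
  raw <- make_raw(matrix(rnorm(nrow(m) * 100), nrow(m), 100))
  out <- interpolate_spherical_spline(raw, "Fp1")
  expect_identical(out$data["C3", ], raw$data["C3", ])
  W1 <- spline_interpolation_weights(m, setdiff(eeg_labels(), "Fp1"), "Fp1")
  W2 <- spline_interpolation_weights(m, setdiff(eeg_labels(), "Fp1"), "Fp1")
  expect_identical(W1, W2)
})

test_that("degenerate geometry and bad inputs error", {
  m <- standard_montage()
  expect_error(spline_interpolation_weights(m, c("C3", "C4", "Cz"), "FT9"),
               "at least 4")
  raw <- make_raw(matrix(0, nrow(m), 10))
  expect_error(interpolate_spherical_spline(raw, "EOGV"), "EEG")
})
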