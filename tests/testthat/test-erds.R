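test_that("ERD/S follows the band-power ratio identities", {
  fs <- 500
  n <- 9 * fs                      # -2..7 s epoch
  t <- (seq_len(n) - 1) / fs - 2
  m <- standard_montage()
  # 10 Hz tone whose amplitude drops to sqrt(1/2) inside 1..7 s: A = R/2
  amp <- ifelse(t >= 1, sqrt(0.5), 1)
  sig <- amp * sin(2 * pi * 10 * t)
  data <- array(0, dim = c(1, nrow(m), n))
  for (ci in seq_len(nrow(m))) data[1, ci, ] <- sig
  ep <- make_epochs(data)
  v <- erds_per_epoch(ep, "alpha")
  expect_equal(unname(v[1, "C3"]), -50, tolerance = 1.5)
  # constant amplitude: A = R -> 0 %
  data0 <- array(rep(sin(2 * pi * 10 * t), each = 1), c(1, nrow(m), n))
  for (ci in seq_len(nrow(m))) data0[1, ci, ] <- sin(2 * pi * 10 * t)
  v0 <- erds_per_epoch(make_epochs(data0), "alpha")
  expect_equal(unname(v0[1, "C3"]), 0, tolerance = 1)
})

test_that("ERD/S is scale invariant and bounded below by -100", {
  set.seed(10)
  m <- standard_montage()
  data <- array(rnorm(4 * nrow(m) * 4500), c(4, nrow(m), 4500))
  ep <- make_epochs(data)
  v1 <- erds_per_epoch(ep, "alpha")
  ep2 <- ep; ep2$data <- ep$data * 7.3
  v2 <- erds_per_epoch(ep2, "alpha")
  expect_equal(v1, v2, tolerance = 1e-10)
  expect_true(all(v1 >= -100))
  vb <- erds_per_epoch(ep, "beta")
  expect_true(all(vb >= -100))
})

test_that("zero reference power yields a reported undefined cell", {
  set.seed(12)
  m <- standard_montage()
  n <- 4500
  data <- array(rnorm(nrow(m) * n), c(1, nrow(m), n))
  data[1, m$channel == "Cz", ] <- 0               # one dead channel
  ep <- make_epochs(data)
  expect_warning(v <- erds_per_epoch(ep, "alpha"), "zero reference")
  expect_true(any(is.na(v)))
  expect_gt(nrow(attr(v, "undefined_cells")), 0)
})

test_that("condition means average kept trials and flag empty conditions", {
  pe <- matrix(c(-10, -30, 5, 7), nrow = 2, byrow = FALSE,
               dimnames = list(NULL, c("C3", "C4")))
  out <- mean_erds_by_condition(pe, c("LEFT", "LEFT"),
                                meta = list(participant = "P1"))
  expect_equal(out$erds_percent[out$level == "C3"], -20)
  # single trial passes through
  out1 <- mean_erds_by_condition(pe[1, , drop = FALSE], "RIGHT")
  expect_equal(out1$erds_percent, unname(pe[1, ]))
  # permuting trials leaves means unchanged
  pe3 <- rbind(pe, c(2, 4))
  cond3 <- c("LEFT", "RIGHT", "LEFT")
  a <- mean_erds_by_condition(pe3, cond3)
  p <- c(3, 1, 2)
  b <- mean_erds_by_condition(pe3[p, ], cond3[p])
  expect_equal(dplyr::arrange(a, condition, level),
               dplyr::arrange(b, condition, level))
  expect_error(
    mean_erds_by_condition(pe, c("LEFT", "LEFT"),
                           expected_conditions = c("LEFT", "BOTH")),
    "BOTH")
})

test_that("ROI means are unweighted channel means", {
  chans <- unlist(roi_set(), use.names = FALSE)
  tab <- tibble::tibble(participant = "P1", condition = "LEFT",
                        level = chans, erds_percent = 0)
  tab$erds_percent[tab$level %in% roi_set()$CL] <- -10
  tab$erds_percent[tab$level %in% roi_set()$FL] <- c(0, 6, 12)
  out <- roi_means(tab)
  expect_equal(out$erds_percent[out$level == "CL"], -10)
  expect_equal(out$erds_percent[out$level == "FL"], 6)
  expect_error(roi_means(tab[tab$level != "C3", ]), "CL")
})

test_that("mirror-symmetric fields give equal left/right ROI means", {
  mirror <- c(Fp1 = "Fp2", F3 = "F4", F7 = "F8", FC1 = "FC2", FC5 = "FC6",
              C3 = "C4", CP1 = "CP2", CP5 = "CP6", P3 = "P4", P7 = "P8",
              O1 = "O2")
  left <- names(mirror)
  set.seed(11)
  vals <- rnorm(length(left), sd = 10)
  tab <- tibble::tibble(
    participant = "P1", condition = "BOTH",
    level = c(left, unname(mirror)),
    erds_percent = c(vals, vals)
  )
  out <- roi_means(tab)
  get <- function(l) out$erds_percent[out$level == l]
  expect_equal(get("FL"), get("FR"))
  expect_equal(get("CL"), get("CR"))
  expect_equal(get("PL"), get("PR"))
})

test_that("grand averages are unweighted means over participants", {
  tab <- tidyr::expand_grid(participant = c("P1", "P2"),
                            group = "lefthanded", task = "MI",
                            band = "alpha", condition = "LEFT", level = "CL")
  tab$erds_percent <- c(-10, -30)
  ga <- grand_average_erds(tab)
  expect_equal(ga$erds_percent, -20)
  expect_equal(ga$n_participants, 2)
})
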