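test_that("Greenhouse-Geisser epsilon has its closed-form limits", {
  cs <- diag(6) * 0.4 + 0.6            # compound symmetry: sphericity holds
  expect_equal(gg_epsilon(cs, 6), 1)
  v <- c(1, 2, 0.5, 1.5, 0.3, 2.2)     # rank-1: maximal violation
  expect_equal(gg_epsilon(v %o% v, 6), 0.2)
  expect_error(gg_epsilon(diag(1), 1), "at least 2")
})

test_that("epsilon on random covariances matches the direct Box formula", {
  set.seed(20)
  for (k in c(3, 6)) {
    for (rep in 1:10) {
      A <- matrix(rnorm(k * k), k)
      S <- crossprod(A) + diag(k) * 0.1
      expect_equal(gg_epsilon(S, k), oracle_gg_epsilon(S), tolerance = 1e-10)
    }
  }
})

test_that("sums of squares match the brute-force projection oracle", {
  for (seed in c(42, 43)) {
    d <- simulate_design_table(n_per_cell = 2, seed = seed)
    a <- mixed_rm_anova(d)
    oracle <- oracle_anova_ss(d)
    tab <- a$table
    for (eff in names(oracle$effects)) {
      got <- tab$ss[tab$effect == eff]
      expect_equal(got, unname(oracle$effects[eff]), tolerance = 1e-8,
                   label = sprintf("SS[%s]", eff))
    }
    for (st in names(oracle$errors)) {
      got <- unique(tab$ss_error[tab$stratum == st])
      expect_equal(got, unname(oracle$errors[st]), tolerance = 1e-8,
                   label = sprintf("SS_err[%s]", st))
    }
    # full decomposition: all components add up to the total SS
    total <- sum((d$erds_percent - mean(d$erds_percent))^2)
    expect_equal(sum(oracle$effects) + sum(oracle$errors), total,
                 tolerance = 1e-8 * total)
    expect_equal(sum(tab$ss) + sum(unique(tab$ss_error)), total,
                 tolerance = 1e-8 * total)
  }
})

test_that("the GG correction reduces significance for F >= 1", {
  d <- simulate_design_table(n_per_cell = 4, seed = 7)
  tab <- mixed_rm_anova(d)$table
  within <- tab[tab$stratum != "none" & tab$F >= 1, ]
  expect_true(all(within$p >= within$p_uncorrected - 1e-12))
  expect_true(all(tab$epsilon >= 0.2 - 1e-12 & tab$epsilon <= 1 + 1e-12))
  expect_true(all(tab$df1_gg <= tab$df1 + 1e-12))
})

test_that("a large ROI effect is detected with high power", {
  effects <- matrix(0, 6, 3)
  effects[1, ] <- 3 * 10                # +3 within-SD shift on one ROI
  hits <- 0
  for (i in 1:60) {
    d <- simulate_design_table(n_per_cell = 7, effects = effects,
                               seed = 1000 + i)
    tab <- mixed_rm_anova(d)$table
    hits <- hits + (tab$p[tab$effect == "roi"] < 0.05)
  }
  expect_gt(hits / 60, 0.95)
})

test_that("marginal means equal raw cell means on balanced designs", {
  # identical values -> every marginal mean = v, SE = 0
  d <- simulate_design_table(n_per_cell = 2, sd_subject = 0, sd_within = 1e-12,
                             seed = 1)
  d$erds_percent <- 4.2
  a <- mixed_rm_anova(d)
  em <- emmeans_erds(a, "roi")
  expect_equal(em$emmean, rep(4.2, 6))
  expect_equal(em$se, rep(0, 6), tolerance = 1e-10)
  # random balanced tables: emmeans equal simple level means (oracle via
  # aggregate), for several effects
  for (seed in 1:5) {
    dd <- simulate_design_table(n_per_cell = 3, seed = 100 + seed)
    aa <- mixed_rm_anova(dd)
    for (eff in c("roi", "condition", "handedness", "roi:condition")) {
      em <- emmeans_erds(aa, eff)
      facs <- strsplit(eff, ":")[[1]]
      oracle <- stats::aggregate(dd$erds_percent, dd[facs], mean)
      key <- do.call(paste, c(em[facs], sep = "."))
      okey <- do.call(paste, c(oracle[facs], sep = "."))
      expect_equal(em$emmean, oracle$x[match(key, okey)], tolerance = 1e-10)
    }
  }
  expect_error(emmeans_erds(a, "banana"), "Unknown effect")
})

test_that("Tukey p-values behave like the studentized range", {
  em <- tibble::tibble(level = c("a", "b", "c"), emmean = c(1, 1, 4))
  out <- tukey_pairwise(em, error_df = 12, error_ms = 3, n_per_mean = 5)
  expect_equal(out$p_tukey[out$level_1 == "a" & out$level_2 == "b"], 1,
               tolerance = 1e-6)
  # relabeling invariance
  em2 <- em[c(3, 1, 2), ]
  out2 <- tukey_pairwise(em2, 12, 3, 5)
  key <- function(x) paste(pmin(x$level_1, x$level_2),
                           pmax(x$level_1, x$level_2))
  expect_equal(out$p_tukey[order(key(out))], out2$p_tukey[order(key(out2))])
  # k = 2 reduces to the ordinary two-sided comparison
  em3 <- tibble::tibble(level = c("a", "b"), emmean = c(1, 2.5))
  tp <- tukey_pairwise(em3, 10, 2, 6)
  expect_equal(tp$p_tukey, 2 * pt(-abs(tp$t), 10), tolerance = 1e-6)
})

test_that("post-hoc comparisons use the right error stratum", {
  d <- simulate_design_table(n_per_cell = 4, seed = 33)
  a <- mixed_rm_anova(d)
  ph <- posthoc_tukey(a, "roi")
  expect_equal(nrow(ph), choose(6, 2))
  expect_true(all(ph$p_tukey >= 0 & ph$p_tukey <= 1))
  # degrees of freedom come from the roi stratum
  tab <- a$table
  expect_error(posthoc_tukey(a, "roi:condition"), "main effects")
})

test_that("invalid designs raise explicit errors", {
  d <- simulate_design_table(n_per_cell = 2, seed = 3)
  expect_error(mixed_rm_anova(d[-1, ]), "Unbalanced")
  d2 <- d; d2$sex <- "female"
  expect_error(mixed_rm_anova(d2), "2 observed levels")
  d3 <- simulate_design_table(n_per_cell = 1, seed = 3)
  expect_error(mixed_rm_anova(d3), "Insufficient replication")
  d4 <- d; d4$erds_percent[1] <- NA
  expect_error(mixed_rm_anova(d4), "missing values")
})

test_that("the four standard analyses run from one tidy table", {
  rows <- list()
  for (seed in 1:4) {
    d <- simulate_design_table(n_per_cell = 2, seed = 200 + seed)
    combo <- tidyr::expand_grid(task = c("ME", "MI"),
                                band = c("alpha", "beta"))[seed, ]
    rows[[seed]] <- tibble::tibble(
      participant = d$participant, group = d$handedness, sex = d$sex,
      task = combo$task, band = combo$band, condition = d$condition,
      level = d$roi, erds_percent = d$erds_percent
    )
  }
  tab <- dplyr::bind_rows(rows)
  res <- run_erds_anovas(tab)
  expect_named(res, c("ME_alpha", "ME_beta", "MI_alpha", "MI_beta"))
  expect_true(all(vapply(res, inherits, logical(1), "erds_anova")))
  g <- glance(res$MI_beta)
  expect_equal(g$n_participants, 8)
  expect_s3_class(tidy(res$ME_alpha), "tbl_df")
})
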