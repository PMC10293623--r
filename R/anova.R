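# Mixed repeated-measures ANOVA for the 6 (ROI) x 3 (Condition) within design
# with Handedness and Sex as between-subject factors, Greenhouse-Geisser
# sphericity correction and Tukey-corrected post-hoc comparisons.

# Orthonormal basis of the contrast space (orthogonal to the constant) for a
# k-level factor: k x (k-1) matrix Q with Q'Q = I, Q'1 = 0.
contrast_basis <- function(k) {
  qr.Q(qr(cbind(rep(1, k), stats::contr.helmert(k))))[, -1, drop = FALSE]
}

#' Greenhouse-Geisser epsilon
#'
#' Box's sample estimate of the sphericity correction factor for a k-level
#' within-subject factor: with `M` the covariance of the within-level scores
#' projected onto an orthonormal contrast basis,
#' `epsilon = tr(M)^2 / ((k - 1) * tr(M %*% M))`, clipped to
#' `[1/(k - 1), 1]`. Under compound symmetry epsilon is 1 (sphericity
#' holds); a rank-one covariance gives the lower bound `1/(k - 1)`.
#'
#' @param cov Either the k x k covariance matrix of the within-level scores
#'   (projected internally), or the (k-1) x (k-1) covariance of orthonormal
#'   contrasts.
#' @param k Number of factor levels.
#' @return Epsilon in `[1/(k - 1), 1]`.
#' @export
gg_epsilon <- function(cov, k) {
  if (k < 2) abort("`k` must be at least 2.")
  cov <- as.matrix(cov)
  if (nrow(cov) == k) {
    Q <- contrast_basis(k)
    M <- t(Q) %*% cov %*% Q
  } else if (nrow(cov) == k - 1) {
    M <- cov
  } else {
    abort("`cov` must be k x k (level scores) or (k-1) x (k-1) (contrasts).")
  }
  gg_epsilon_contrast(M)
}

# Box epsilon on an already contrast-projected covariance (d = dim of the
# contrast space; the lower bound is 1/d).
gg_epsilon_contrast <- function(M) {
  d <- nrow(M)
  eps <- sum(diag(M))^2 / (d * sum(M * M))
  min(max(eps, 1 / d), 1)
}

# Pooled within-cell covariance of subject-level score matrices.
# `scores`: subjects x levels; `cell`: between-cell id per subject.
pooled_within_cov <- function(scores, cell) {
  cells <- split(seq_len(nrow(scores)), cell)
  centred <- scores
  for (ix in cells) {
    centred[ix, ] <- sweep(scores[ix, , drop = FALSE], 2,
                           colMeans(scores[ix, , drop = FALSE]))
  }
  crossprod(centred) / (nrow(scores) - length(cells))
}

# Subject-level score matrix for a set of within-factor levels: value
# averaged over the within factors *not* in `within`, one column per level
# combination of `within` (ordered), one row per subject.
subject_scores <- function(data, within) {
  lvls <- lapply(within, function(w) sort(unique(as.character(data[[w]]))))
  grid <- rev(expand.grid(rev(lvls), stringsAsFactors = FALSE))  # first factor major
  keys <- do.call(paste, c(grid, sep = "_"))
  key <- factor(do.call(paste, c(lapply(within, function(w) {
    as.character(data[[w]])
  }), sep = "_")), levels = keys)
  tapply(data$.value, list(factor(as.character(data$participant)), key), mean)
}

validate_long_design <- function(data, dv) {
  req <- c("participant", "handedness", "sex", "roi", "condition", dv)
  missing <- setdiff(req, names(data))
  if (length(missing)) {
    abort(sprintf("Design table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyNA(data[[dv]])) abort("Design table contains missing values.")
  k_roi <- dplyr::n_distinct(data$roi)
  k_cond <- dplyr::n_distinct(data$condition)
  counts <- data |>
    dplyr::count(.data$participant, .data$roi, .data$condition)
  if (any(counts$n != 1) ||
      nrow(counts) != dplyr::n_distinct(data$participant) * k_roi * k_cond) {
    abort("Unbalanced design: every participant needs exactly one value per ROI x condition cell.")
  }
  between <- data |>
    dplyr::distinct(.data$participant, .data$handedness, .data$sex)
  if (anyDuplicated(between$participant)) {
    abort("Each participant must have a single handedness and sex.")
  }
  if (dplyr::n_distinct(between$handedness) < 2 ||
      dplyr::n_distinct(between$sex) < 2) {
    abort("Both between-subject factors need at least 2 observed levels.")
  }
  cell_n <- between |> dplyr::count(.data$handedness, .data$sex)
  if (nrow(cell_n) < 4 || any(cell_n$n < 2)) {
    abort("Insufficient replication: need >= 2 participants in every handedness x sex cell.")
  }
  invisible(between)
}

#' Mixed repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fits the split-plot ANOVA for a complete balanced design with
#' within-subject factors ROI and condition and between-subject factors
#' handedness and sex, partitioning sums of squares into the participant
#' (between), participant:roi, participant:condition and
#' participant:roi:condition error strata. All within effects (and
#' interactions involving them) are reported with Greenhouse-Geisser
#' corrected degrees of freedom and p-values; epsilon for interactions is
#' computed on the Kronecker product of the factors' contrast spaces.
#'
#' @param data Long tibble with columns `participant`, `handedness`, `sex`,
#'   `roi`, `condition` and the response column `dv`.
#' @param dv Name of the response column (default `"erds_percent"`).
#' @return Object of class `erds_anova` with an effect table (see
#'   [tidy.erds_anova()]), epsilon estimates, and the data needed for
#'   [emmeans_erds()] and [posthoc_tukey()].
#' @export
mixed_rm_anova <- function(data, dv = "erds_percent") {
  between <- validate_long_design(data, dv)
  d <- data
  d$.value <- d[[dv]]
  d$participant <- factor(d$participant)
  d$handedness <- factor(d$handedness)
  d$sex <- factor(d$sex)
  d$roi <- factor(d$roi)
  d$condition <- factor(d$condition)

  fit <- stats::aov(
    .value ~ roi * condition * handedness * sex +
      Error(participant / (roi * condition)),
    data = d
  )
  strata <- summary(fit)

  k_roi <- nlevels(d$roi)
  k_cond <- nlevels(d$condition)
  cell_of <- function(p) {
    b <- between[match(p, between$participant), ]
    paste(b$handedness, b$sex)
  }
  Q_roi <- contrast_basis(k_roi)
  Q_cond <- contrast_basis(k_cond)

  sc_roi <- subject_scores(d, "roi")
  sc_cond <- subject_scores(d, "condition")
  sc_rc <- subject_scores(d, c("roi", "condition"))
  cellv <- cell_of(rownames(sc_roi))
  eps <- c(
    none = 1,
    roi = gg_epsilon_contrast(
      t(Q_roi) %*% pooled_within_cov(sc_roi, cellv) %*% Q_roi),
    condition = gg_epsilon_contrast(
      t(Q_cond) %*% pooled_within_cov(sc_cond, cellv) %*% Q_cond),
    `roi:condition` = gg_epsilon_contrast(
      t(Q_roi %x% Q_cond) %*% pooled_within_cov(sc_rc, cellv) %*%
        (Q_roi %x% Q_cond))
  )

  stratum_of <- function(effect) {
    has_roi <- grepl("(^|:)roi($|:)", effect)
    has_cond <- grepl("(^|:)condition($|:)", effect)
    if (has_roi && has_cond) "roi:condition" else if (has_roi) "roi"
    else if (has_cond) "condition" else "none"
  }

  rows <- list()
  for (sname in names(strata)) {
    tab <- strata[[sname]][[1]]
    effects <- trimws(rownames(tab))
    res_i <- which(effects == "Residuals")
    if (length(res_i) == 0) next
    ms_err <- tab[res_i, "Mean Sq"]
    df_err <- tab[res_i, "Df"]
    ss_err <- tab[res_i, "Sum Sq"]
    for (i in setdiff(seq_along(effects), res_i)) {
      eff <- effects[i]
      st <- stratum_of(eff)
      e <- eps[[st]]
      F_val <- tab[i, "Mean Sq"] / ms_err
      df1 <- tab[i, "Df"]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        effect = eff, stratum = st,
        ss = tab[i, "Sum Sq"], df1 = df1, df2 = df_err,
        ss_error = ss_err,
        F = F_val, epsilon = e,
        df1_gg = e * df1, df2_gg = e * df_err,
        p_uncorrected = pf(F_val, df1, df_err, lower.tail = FALSE),
        p = pf(F_val, e * df1, e * df_err, lower.tail = FALSE)
      )
    }
  }
  table <- dplyr::bind_rows(rows)

  structure(
    list(table = table, epsilon = eps, data = d, between = between,
         k = c(roi = k_roi, condition = k_cond),
         n_participants = nrow(between),
         strata = strata, alpha = 0.05),
    class = "erds_anova"
  )
}

#' @export
print.erds_anova <- function(x, ...) {
  cat(sprintf("Mixed RM-ANOVA: %d participants, %d x %d within design (GG-corrected)\n",
              x$n_participants, x$k["roi"], x$k["condition"]))
  tab <- x$table
  cat(sprintf("%-34s %8s %14s %7s %8s\n", "effect", "F", "df (GG)", "eps", "p"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("%-34s %8.3f (%6.2f,%6.2f) %7.3f %8.4f%s\n",
                tab$effect[i], tab$F[i], tab$df1_gg[i], tab$df2_gg[i],
                tab$epsilon[i], tab$p[i],
                ifelse(tab$p[i] < x$alpha, " *", "")))
  }
  invisible(x)
}

#' Tidy an ANOVA result
#'
#' @param x An `erds_anova` object.
#' @param ... Unused.
#' @return Tibble with one row per effect: `effect`, `stratum`, `ss`, `df1`,
#'   `df2`, `F`, `epsilon`, GG-corrected `df1_gg`/`df2_gg`,
#'   `p_uncorrected` and corrected `p`.
#' @export
tidy.erds_anova <- function(x, ...) {
  x$table
}

#' Glance at an ANOVA result
#'
#' @param x An `erds_anova` object.
#' @param ... Unused.
#' @return One-row tibble with design size and the three epsilon estimates.
#' @export
glance.erds_anova <- function(x, ...) {
  tibble::tibble(
    n_participants = x$n_participants,
    k_roi = unname(x$k["roi"]),
    k_condition = unname(x$k["condition"]),
    epsilon_roi = unname(x$epsilon["roi"]),
    epsilon_condition = unname(x$epsilon["condition"]),
    epsilon_interaction = unname(x$epsilon["roi:condition"])
  )
}

# Factors of an effect string, validated against the design.
effect_factors <- function(object, effect) {
  facs <- strsplit(effect, ":", fixed = TRUE)[[1]]
  known <- c("roi", "condition", "handedness", "sex")
  if (!length(facs) || !all(facs %in% known)) {
    abort(sprintf("Unknown effect '%s'.", effect))
  }
  facs
}

#' Estimated marginal means
#'
#' Marginal means of an effect with standard errors. For a balanced design
#' these equal the raw cell means averaged (unweighted) over the non-focal
#' factors. The standard error of each marginal mean is computed from the
#' subject-level scores at that level: scores are the per-subject means over
#' the non-focal within factors, their variance is pooled within
#' between-subject cells (df = N - G cells), and the between-cell averaging
#' is propagated.
#'
#' @param object An [mixed_rm_anova()] result.
#' @param effect Effect name, e.g. `"roi"`, `"condition"`, `"handedness"`,
#'   or an interaction like `"roi:condition"` or `"roi:handedness"`.
#' @return Tibble with the effect's factor columns plus `emmean`, `se`, `df`.
#' @export
emmeans_erds <- function(object, effect) {
  facs <- effect_factors(object, effect)
  within <- intersect(facs, c("roi", "condition"))
  between_facs <- intersect(facs, c("handedness", "sex"))
  d <- object$data
  between <- object$between
  G <- nrow(dplyr::distinct(between, .data$handedness, .data$sex))
  N <- object$n_participants

  scores <- if (length(within)) {
    subject_scores(d, within)
  } else {
    m <- subject_scores(d, "roi")  # any; then average all levels
    matrix(rowMeans(m), ncol = 1, dimnames = list(rownames(m), "all"))
  }
  binfo <- between[match(rownames(scores), between$participant), ]
  cellv <- paste(binfo$handedness, binfo$sex)

  level_grid <- if (length(within)) {
    d |>
      dplyr::distinct(dplyr::across(dplyr::all_of(within))) |>
      dplyr::arrange(dplyr::across(dplyr::all_of(within))) |>
      tidyr::unite(".wcell", dplyr::all_of(within), remove = FALSE)
  } else {
    tibble::tibble(.wcell = "all")
  }
  # within-level column names follow subject_scores (unite with "_")
  level_grid$.col <- if (length(within)) {
    apply(level_grid[within], 1, paste, collapse = "_")
  } else "all"

  bgrid <- if (length(between_facs)) {
    dplyr::distinct(between, dplyr::across(dplyr::all_of(between_facs))) |>
      dplyr::arrange(dplyr::across(dplyr::all_of(between_facs)))
  } else {
    tibble::tibble(.dummy = 1L)
  }

  out <- list()
  for (bi in seq_len(nrow(bgrid))) {
    sel <- rep(TRUE, nrow(binfo))
    for (bf in between_facs) sel <- sel & binfo[[bf]] == bgrid[[bf]][bi]
    cells <- unique(cellv[sel])
    for (li in seq_len(nrow(level_grid))) {
      z <- scores[, level_grid$.col[li]]
      s2 <- pooled_level_var(z, cellv)        # pooled over all G cells
      cell_means <- vapply(cells, function(cc) mean(z[sel & cellv == cc]),
                           numeric(1))
      cell_ns <- vapply(cells, function(cc) sum(sel & cellv == cc), numeric(1))
      emmean <- mean(cell_means)
      se <- sqrt(s2 * sum(1 / cell_ns) / length(cells)^2)
      row <- tibble::tibble(emmean = emmean, se = se, df = N - G)
      for (wf in rev(within)) {
        row <- tibble::add_column(row, !!wf := level_grid[[wf]][li],
                                  .before = 1)
      }
      for (bf in rev(between_facs)) {
        row <- tibble::add_column(row, !!bf := bgrid[[bf]][bi], .before = 1)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  dplyr::bind_rows(out)
}

# Variance of subject scores pooled within between-cells (df = N - G).
pooled_level_var <- function(z, cellv) {
  ssq <- 0
  for (cc in unique(cellv)) {
    zi <- z[cellv == cc]
    ssq <- ssq + sum((zi - mean(zi))^2)
  }
  ssq / (length(z) - length(unique(cellv)))
}

#' Tukey-corrected pairwise comparisons from marginal means
#'
#' All pairwise comparisons among a set of level means, with p-values from
#' the studentized-range distribution: `t = diff / sqrt(2 MS / n)` and
#' `p = P(q_{k, df} >= |t| sqrt(2))`. For k = 2 this reduces to the ordinary
#' two-sided comparison from the same error stratum. Symmetric in pair order
#' and invariant to level relabeling.
#'
#' @param emm Tibble with one factor column (the first column) and an
#'   `emmean` column, e.g. a single-factor [emmeans_erds()] result.
#' @param error_df Error degrees of freedom.
#' @param error_ms Error mean square (on the observation scale).
#' @param n_per_mean Number of observations underlying each level mean.
#' @return Tibble with `level_1`, `level_2`, `estimate`, `se`, `t`,
#'   `p_tukey`.
#' @export
tukey_pairwise <- function(emm, error_df, error_ms, n_per_mean) {
  levels <- as.character(emm[[1]])
  means <- emm$emmean
  k <- length(levels)
  if (k < 2) abort("Need at least 2 levels for pairwise comparisons.")
  pairs <- utils::combn(k, 2)
  se <- sqrt(2 * error_ms / n_per_mean)
  tibble::tibble(
    level_1 = levels[pairs[1, ]],
    level_2 = levels[pairs[2, ]],
    estimate = means[pairs[1, ]] - means[pairs[2, ]],
    se = se,
    t = estimate / se,
    p_tukey = ptukey(abs(t) * sqrt(2), nmeans = k, df = error_df,
                     lower.tail = FALSE)
  )
}

#' Tukey post-hoc comparisons for a fitted effect
#'
#' Convenience wrapper computing all pairwise comparisons within a main
#' effect of the fitted design, using that effect's own error stratum: the
#' within-stratum residual mean square for `roi`/`condition`, the
#' between-participant residual for `handedness`/`sex`.
#'
#' @param object An [mixed_rm_anova()] result.
#' @param effect A main-effect name.
#' @return Tibble as from [tukey_pairwise()].
#' @export
posthoc_tukey <- function(object, effect) {
  facs <- effect_factors(object, effect)
  if (length(facs) > 1) {
    abort("posthoc_tukey() handles main effects; use tukey_pairwise() on cell means for interactions.")
  }
  emm <- emmeans_erds(object, effect)
  d <- object$data
  N <- object$n_participants
  k_roi <- object$k["roi"]
  k_cond <- object$k["condition"]
  stratum_name <- switch(effect,
    roi = "Error: participant:roi",
    condition = "Error: participant:condition",
    "Error: participant"
  )
  tab <- object$strata[[stratum_name]][[1]]
  res <- tab[trimws(rownames(tab)) == "Residuals", , drop = FALSE]
  n_per_mean <- switch(effect,
    roi = N * k_cond,
    condition = N * k_roi,
    handedness = ,
    sex = (N / 2) * k_roi * k_cond
  )
  tukey_pairwise(emm, res[, "Df"], res[, "Mean Sq"], n_per_mean)
}

#' Run the four RM-ANOVAs of the standard analysis
#'
#' One mixed RM-ANOVA per task (ME, MI) and band (alpha, beta), all driven by
#' the same ROI-level ERD/S table.
#'
#' @param roi_table Tidy ROI-level ERD/S table with columns `participant`,
#'   `group` (handedness), `sex`, `task`, `band`, `condition`, `level`,
#'   `erds_percent`.
#' @return Named list of `erds_anova` objects (`ME_alpha`, `ME_beta`,
#'   `MI_alpha`, `MI_beta`); entries whose design is invalid hold the error
#'   condition instead.
#' @export
run_erds_anovas <- function(roi_table) {
  combos <- tidyr::expand_grid(task = c("ME", "MI"), band = c("alpha", "beta"))
  out <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- roi_table |>
      dplyr::filter(.data$task == combos$task[i], .data$band == combos$band[i]) |>
      dplyr::transmute(participant = .data$participant,
                       handedness = .data$group, sex = .data$sex,
                       roi = .data$level, condition = .data$condition,
                       erds_percent = .data$erds_percent)
    nm <- paste(combos$task[i], combos$band[i], sep = "_")
    out[[nm]] <- tryCatch(mixed_rm_anova(sub), error = function(e) e)
  }
  out
}
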