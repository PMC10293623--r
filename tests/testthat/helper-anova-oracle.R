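# Brute-force projection oracle for the balanced split-plot sums of squares:
# each fixed effect's SS is obtained by explicit least-squares projection of
# the response onto that effect's Helmert-contrast design block (blocks are
# mutually orthogonal in a balanced design), and each error stratum's SS by
# subtracting the effects from the stratum total. Independent of the
# package's aov-based route.
oracle_anova_ss <- function(d, dv = "erds_percent") {
  y <- d[[dv]]
  f <- lapply(d[c("roi", "condition", "handedness", "sex")], factor)
  contr <- lapply(f, function(ff) stats::contr.helmert(nlevels(ff)))
  block <- function(facs) {
    Z <- matrix(1, nrow(d), 1)
    for (fac in facs) {
      C <- contr[[fac]][as.integer(f[[fac]]), , drop = FALSE]
      Znew <- matrix(0, nrow(d), ncol(Z) * ncol(C))
      for (i in seq_len(ncol(Z))) {
        for (j in seq_len(ncol(C))) {
          Znew[, (i - 1) * ncol(C) + j] <- Z[, i] * C[, j]
        }
      }
      Z <- Znew
    }
    Z
  }
  proj_ss <- function(Z) {
    yc <- y - mean(y)
    fit <- Z %*% solve(crossprod(Z), crossprod(Z, yc))
    sum(fit^2)
  }
  effects <- list(
    handedness = "handedness", sex = "sex",
    `handedness:sex` = c("handedness", "sex"),
    roi = "roi",
    `roi:handedness` = c("roi", "handedness"),
    `roi:sex` = c("roi", "sex"),
    `roi:handedness:sex` = c("roi", "handedness", "sex"),
    condition = "condition",
    `condition:handedness` = c("condition", "handedness"),
    `condition:sex` = c("condition", "sex"),
    `condition:handedness:sex` = c("condition", "handedness", "sex"),
    `roi:condition` = c("roi", "condition"),
    `roi:condition:handedness` = c("roi", "condition", "handedness"),
    `roi:condition:sex` = c("roi", "condition", "sex"),
    `roi:condition:handedness:sex` = c("roi", "condition", "handedness", "sex")
  )
  ss <- vapply(effects, function(facs) proj_ss(block(facs)), numeric(1))

  # stratum totals from subject-level means
  a <- nlevels(f$roi); b <- nlevels(f$condition)
  m_s <- tapply(y, d$participant, mean)
  m_si <- tapply(y, list(d$participant, d$roi), mean)
  m_sj <- tapply(y, list(d$participant, d$condition), mean)
  gm <- mean(y)
  tot_between <- a * b * sum((m_s - gm)^2)
  tot_roi <- b * sum((m_si - as.vector(m_s[rownames(m_si)]))^2)
  tot_cond <- a * sum((m_sj - as.vector(m_s[rownames(m_sj)]))^2)
  resid_sij <- y -
    m_si[cbind(as.character(d$participant), as.character(d$roi))] -
    m_sj[cbind(as.character(d$participant), as.character(d$condition))] +
    as.vector(m_s[as.character(d$participant)])
  tot_rc <- sum(resid_sij^2)
  err <- c(
    none = tot_between - ss["handedness"] - ss["sex"] - ss["handedness:sex"],
    roi = tot_roi - ss["roi"] - ss["roi:handedness"] - ss["roi:sex"] -
      ss["roi:handedness:sex"],
    condition = tot_cond - ss["condition"] - ss["condition:handedness"] -
      ss["condition:sex"] - ss["condition:handedness:sex"],
    `roi:condition` = tot_rc - ss["roi:condition"] -
      ss["roi:condition:handedness"] - ss["roi:condition:sex"] -
      ss["roi:condition:handedness:sex"]
  )
  names(err) <- c("none", "roi", "condition", "roi:condition")
  list(effects = ss, errors = err)
}

# Direct Box formula via eigenvalues of the double-centred covariance — an
# independent route to the Greenhouse-Geisser epsilon.
oracle_gg_epsilon <- function(S) {
  k <- nrow(S)
  J <- diag(k) - matrix(1 / k, k, k)
  lam <- eigen(J %*% S %*% J, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[seq_len(k - 1)]
  min(max(sum(lam)^2 / ((k - 1) * sum(lam^2)), 1 / (k - 1)), 1)
}
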