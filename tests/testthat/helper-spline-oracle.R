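# Independent dense evaluation of the spherical-spline kernel, using
# pracma's Legendre functions and an explicit matrix inverse — a different
# route from the package's recurrence + linear solve.
oracle_weights <- function(montage, good, bad, m = 4, n_terms = 50,
                           lambda = 1e-5) {
  pos <- as.matrix(montage[match(c(good, bad), montage$channel),
                           c("x", "y", "z")])
  g_fun <- function(x) {
    x <- pmin(1, pmax(-1, as.vector(x)))
    acc <- numeric(length(x))
    for (n in seq_len(n_terms)) {
      p_n <- pracma::legendre(n, x)[1, ]    # P_n^0 row
      acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_n
    }
    acc / (4 * pi)
  }
  ng <- length(good)
  pg <- pos[seq_len(ng), , drop = FALSE]
  pb <- pos[-seq_len(ng), , drop = FALSE]
  G <- matrix(g_fun(tcrossprod(pg)), ng, ng)
  Gb <- matrix(g_fun(pb %*% t(pg)), nrow(pb), ng)
  A <- rbind(cbind(G + diag(lambda, ng), 1), c(rep(1, ng), 0))
  Ainv <- solve(A)
  (cbind(Gb, 1) %*% Ainv)[, seq_len(ng), drop = FALSE]
}
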