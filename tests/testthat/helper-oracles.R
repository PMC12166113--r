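# Independent oracles used across the suite.  These deliberately use naive
# dense-matrix / term-by-term arithmetic, not the package's code paths.

# Dense-matrix evaluation of the pseudo-score statistic:
# s0 = phibar' (I - A) y / sqrt(sigma2 * phibar' (I - A) phibar),
# with A = X (X'X)^-1 X' built explicitly.
oracle_s0_dense <- function(y, z, X, grid, kind = "jump", sigma2 = NULL) {
  n <- length(y)
  A <- X %*% solve(t(X) %*% X) %*% t(X)
  phi <- sapply(grid, function(pk) {
    if (kind == "jump") as.numeric(z > pk) else pmax(z - pk, 0)
  })
  phibar <- rowMeans(matrix(phi, nrow = n))
  M <- diag(n) - A
  if (is.null(sigma2))                       # H0 residual variance
    sigma2 <- drop(t(y) %*% M %*% y) / (n - ncol(X))
  num <- drop(t(phibar) %*% M %*% y)
  den <- sqrt(sigma2 * drop(t(phibar) %*% M %*% phibar))
  num / den
}

# Textbook pooled two-sample t (equal-variance), via stats::t.test.
oracle_pooled_t <- function(y, j) {
  n <- length(y)
  unname(stats::t.test(y[1:j], y[(j + 1):n], var.equal = TRUE)$statistic)
}

# Term-by-term Rasch Bernoulli log-likelihood.
oracle_rasch_ll <- function(scores, b, theta) {
  p <- 1 / (1 + exp(-(theta - b)))
  sum(ifelse(scores == 1, log(p), log(1 - p)))
}

# Root of the Rasch score equation sum(y - P(theta)) = 0.
oracle_theta_root <- function(scores, b) {
  stats::uniroot(function(t) sum(scores - 1 / (1 + exp(-(t - b)))),
                 c(-6, 6), tol = 1e-10)$root
}

make_jump_series <- function(n, delta, seed, psi = 0.5) {
  set.seed(seed)
  z <- seq_len(n) / n
  cp_series(2 + delta * (z > psi) + rnorm(n), z = z)
}
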