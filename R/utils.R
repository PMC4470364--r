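# Internal numeric helpers shared across modules.

# log(sum(exp(x))) guarding against -Inf-only input
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Cholesky with an explicit positive-definiteness error.
chol_pd <- function(S, what = "matrix") {
  S <- (S + t(S)) / 2
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    abort(sprintf("%s is not symmetric positive-definite", what),
          class = "pwabc_not_pd")
  }
  R
}

logdet_pd <- function(S, what = "matrix") {
  2 * sum(log(diag(chol_pd(S, what))))
}

# Inverse via Cholesky; errors if not PD.
inv_pd <- function(S, what = "matrix") {
  chol2inv(chol_pd(S, what))
}

# Multivariate normal log-density, theta a matrix with one row per point.
mvn_logpdf <- function(theta, mu, Sigma) {
  theta <- as_theta_matrix(theta)
  d <- ncol(theta)
  R <- chol_pd(Sigma, "covariance")
  z <- backsolve(R, t(theta) - mu, transpose = TRUE) # d x N
  -0.5 * d * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(z^2)
}

# n draws from N(mu, Sigma), returned as n x d matrix. Uses the current RNG
# stream so callers control reproducibility with set.seed().
mvn_sample <- function(n, mu, Sigma) {
  d <- length(mu)
  R <- chol_pd(Sigma, "covariance")
  z <- matrix(rnorm(n * d), n, d)
  sweep(z %*% R, 2, mu, `+`)
}

# Coerce parameter input (vector = single point, or matrix N x d) to matrix.
as_theta_matrix <- function(theta, d = NULL) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  theta <- as.matrix(theta)
  if (!is.null(d) && ncol(theta) != d) {
    abort(sprintf("expected %d parameter column(s), got %d", d, ncol(theta)))
  }
  if (!all(is.finite(theta))) abort("parameter values must be finite")
  theta
}

# Deterministic per-factor seed derived from a master seed: a splitmix-style
# integer mix reduced modulo 2^31 - 1, stable across platforms and versions.
factor_seed <- function(master_seed, i) {
  m31 <- 2147483647
  s <- (as.double(master_seed) %% m31)
  s <- (s * 2654435761 + as.double(i) * 40503 + 97) %% m31
  s <- (s * 69069 + 1234567) %% m31
  as.integer(s)
}
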