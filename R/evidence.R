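#' Normalising constant of the epsilon-ball acceptance kernel
#'
#' The acceptance kernel is the uniform density on the \eqn{L^p} ball of
#' radius `epsilon` in the `u`-dimensional state space; `V` is its
#' normaliser, so that the kernel integrates (continuous states) or sums
#' (discrete states) to one. Continuous: the closed-form ball volume
#' \eqn{(2\epsilon)^u \Gamma(1 + 1/p)^u / \Gamma(1 + u/p)}. Discrete: the
#' number of integer lattice points `z` with \eqn{\|z\|_p \le \epsilon}
#' (so `V = 1` at `epsilon = 0`, the exact-match case). Discrete
#' enumeration is supported for `epsilon <= 10`.
#'
#' @param epsilon ball radius (>= 0; `0` only for discrete states).
#' @param p norm order in `[1, Inf]`.
#' @param u state dimension.
#' @param discrete is the state space integer-valued?
#' @return The positive scalar `V`.
#' @examples
#' ball_normaliser(0.1, p = 2, u = 2, discrete = FALSE) # pi * 0.01
#' ball_normaliser(0, p = 2, u = 3, discrete = TRUE)    # 1
#' @export
ball_normaliser <- function(epsilon, p, u, discrete) {
  stopifnot(epsilon >= 0, u >= 1)
  if (p < 1) abort("norm order p must be >= 1")
  if (discrete) {
    if (epsilon > 10) abort("discrete ball enumeration supported for epsilon <= 10")
    r <- floor(epsilon)
    pts <- as.matrix(expand.grid(rep(list(seq(-r, r)), u)))
    nrm <- if (is.infinite(p)) apply(abs(pts), 1, max) else
      rowSums(abs(pts)^p)^(1 / p)
    sum(nrm <= epsilon)
  } else {
    if (epsilon == 0) abort("epsilon = 0 gives a zero-volume ball for continuous states")
    if (is.infinite(p)) {
      (2 * epsilon)^u
    } else {
      exp(u * log(2 * epsilon) + u * lgamma(1 + 1 / p) - lgamma(1 + u / p))
    }
  }
}

#' Per-factor normalising-constant estimate
#'
#' The factor normalising constant \eqn{c_i = \int \pi(x_i | x_{i-1},
#' \theta)\pi(\theta)d\theta} is estimated from the rejection sampler's
#' bookkeeping as \eqn{\hat c_i = m / (V M_i)}, where `M_i` is the number of
#' prior draws needed for `m` acceptances and `V` the ball normaliser.
#' Returned on the log scale.
#'
#' @param m accepted draws.
#' @param M_i total attempts for this factor (`M_i >= m`).
#' @param V ball normaliser from [ball_normaliser()].
#' @return `log(m) - log(V) - log(M_i)`.
#' @export
estimate_log_c <- function(m, M_i, V) {
  stopifnot(V > 0, m >= 1)
  if (M_i < m) abort("attempt count M_i cannot be smaller than m")
  log(m) - log(V) - log(M_i)
}

#' Summed log normalising constants of a fit
#'
#' Convenience wrapper computing \eqn{\sum_i \log\hat c_i} over every factor
#' of a [pwabc_run()] fit, with `V` derived from the fit's tolerance, norm
#' order and state space.
#'
#' @param fit a `pwabc_fit`.
#' @return The scalar \eqn{\sum_i \log\hat c_i}.
#' @export
sum_log_c <- function(fit) {
  stopifnot(inherits(fit, "pwabc_fit"))
  V <- ball_normaliser(fit$config$epsilon, fit$config$p,
                       fit$model$state_dim, fit$model$discrete)
  sum(purrr::map_dbl(fit$factors,
                     ~ estimate_log_c(.x$m, .x$attempts, V)))
}
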