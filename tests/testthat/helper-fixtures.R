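# Shared fixtures, all generated in code at test time.

# A transition model whose simulated next state always equals a fixed target:
# the likelihood is constant in theta, so accepted ABC draws are prior draws.
constant_hit_model <- function(target, d = 1L) {
  structure(
    list(name = "constant_hit", d = d, state_dim = length(target),
         discrete = TRUE, param_names = paste0("theta_", seq_len(d)),
         simulate = function(theta, x_prev, t_prev, t_next) {
           matrix(rep(target, each = nrow(theta)), nrow(theta))
         },
         density = function(x_next, x_prev, dt, theta) {
           rep(as.numeric(all(x_next == target)), nrow(theta))
         },
         cdf = NULL, default_theta = numeric(d), default_x0 = target,
         default_times = as.numeric(1:5),
         default_prior = function() prior_normal(numeric(d), diag(d))),
    class = "pwabc_model")
}

# Identity-dynamics model: the next state always equals the previous state.
identity_model <- function(u = 1L) {
  structure(
    list(name = "identity", d = 1L, state_dim = u, discrete = TRUE,
         param_names = "theta",
         simulate = function(theta, x_prev, t_prev, t_next) {
           matrix(rep(as.numeric(x_prev), each = nrow(theta)), nrow(theta))
         },
         density = function(x_next, x_prev, dt, theta) {
           rep(as.numeric(all(x_next == x_prev)), nrow(theta))
         },
         cdf = NULL, default_theta = 0, default_x0 = rep(1, u),
         default_times = as.numeric(1:5),
         default_prior = function() prior_normal(0, 1)),
    class = "pwabc_model")
}

# Grid quadrature of a single binomial factor phi_i(theta) ~ Binom(x; k,
# expit(theta)) * N(theta; 0, sd^2), normalised on the grid. Independent
# 1-D oracle for the rejection sampler.
binomial_factor_grid <- function(x_obs, k = 100, sd_pri = 3,
                                 lo = -8, hi = 8, res = 4001) {
  th <- seq(lo, hi, length.out = res)
  f <- dbinom(x_obs, k, pwabc::expit(th)) * dnorm(th, 0, sd_pri)
  dth <- th[2] - th[1]
  list(theta = th, density = f / (sum(f) * dth), step = dth,
       c_i = sum(f) * dth)
}

# Sup-norm distance between the ECDF of draws and a grid CDF.
ecdf_vs_grid_sup <- function(draws, grid_theta, grid_density, step) {
  cdf_grid <- cumsum(grid_density) * step
  ec <- stats::ecdf(draws)
  max(abs(ec(grid_theta) - cdf_grid))
}

# Small cached binomial fit reused across test files.
.fixture_env <- new.env()
binomial_fit_small <- function() {
  if (is.null(.fixture_env$binfit)) {
    mod <- binomial_model()
    dat <- generate_series(mod, seed = 7)
    .fixture_env$binmod <- mod
    .fixture_env$bindat <- dat
    .fixture_env$binfit <- pwabc_run(
      dat, mod, config = abc_config(epsilon = 0, m = 600, batch_size = 2e4),
      seed = 3)
  }
  list(model = .fixture_env$binmod, data = .fixture_env$bindat,
       fit = .fixture_env$binfit)
}
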