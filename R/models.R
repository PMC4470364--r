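#' Markov transition models
#'
#' Constructors for the discretely observed Markov models used throughout the
#' package. Each model bundles a vectorised transition simulator (used by the
#' rejection sampler), the exact transition density when it is tractable
#' (used by the exact-posterior oracles), and the default study design:
#' generating parameters on the transformed inference scale, initial state,
#' observation times, and a default prior.
#'
#' Inference is always on a transformed, unconstrained scale and priors are
#' placed directly on the transformed parameter, so no Jacobian corrections
#' appear anywhere:
#'
#' * `binomial_model()`: IID counts \eqn{X_i ~ Binomial(k, p)} with
#'   \eqn{\theta = logit(p)}. Registered as a unit-lag Markov model whose
#'   transition ignores the previous state (IID data as a special case).
#' * `cir_model()`: the Cox--Ingersoll--Ross interest-rate diffusion
#'   \eqn{dX = a(b - X)dt + \sigma\sqrt{X}dW} with \eqn{a, \sigma} known and
#'   \eqn{\theta = \log b}. Transitions are simulated exactly from the known
#'   scaled noncentral chi-square transition law (no discretisation bias);
#'   an Euler--Maruyama fallback is selectable via `method = "euler"`.
#' * `inar1_model()`: the INAR(1) count series
#'   \eqn{X_t = \alpha \circ X_{t-1} + Z_t} with binomial thinning
#'   \eqn{\alpha \circ W ~ Binomial(W, \alpha)} and Poisson immigration
#'   \eqn{Z_t ~ Po(\lambda)}; \eqn{\theta = (logit \alpha, \log\lambda)}.
#' * `lv_model()`: the stochastic Lotka--Volterra jump process with reactions
#'   prey birth (rate \eqn{r_1 Y_1}), predation (\eqn{r_2 Y_1 Y_2}) and
#'   predator death (\eqn{r_3 Y_2}), simulated exactly with the Gillespie
#'   algorithm; \eqn{\theta = (\log r_1, \log r_2, \log r_3)}. No tractable
#'   transition density exists for this model.
#'
#' @param k binomial number of trials.
#' @param a,sigma known CIR reversion speed and volatility.
#' @param method CIR simulation method: `"exact"` (noncentral chi-square) or
#'   `"euler"` (full-truncation Euler--Maruyama with `n_steps` substeps).
#' @param n_steps number of Euler substeps per observation interval.
#'
#' @return An object of class `pwabc_model`: a list with elements `name`,
#'   `d` (parameter dimension), `state_dim`, `discrete`, `param_names`,
#'   the simulator, the transition density (or `NULL`), and default design
#'   fields `default_theta`, `default_x0`, `default_times`, `default_prior`.
#'
#' @examples
#' mod <- binomial_model()
#' simulate_transition(mod, x_prev = NA, t_prev = 0, t_next = 1,
#'                     theta = logit(0.6), seed = 1)
#' @name models
NULL

new_model <- function(name, d, state_dim, discrete, param_names,
                      simulate, density = NULL, cdf = NULL,
                      default_theta, default_x0, default_times,
                      default_prior) {
  structure(
    list(name = name, d = d, state_dim = state_dim, discrete = discrete,
         param_names = param_names, simulate = simulate, density = density,
         cdf = cdf, default_theta = default_theta, default_x0 = default_x0,
         default_times = default_times, default_prior = default_prior),
    class = "pwabc_model")
}

#' @export
print.pwabc_model <- function(x, ...) {
  cat(sprintf("<pwabc model: %s>\n", x$name))
  cat(sprintf("  parameters (d = %d): %s\n", x$d,
              paste(x$param_names, collapse = ", ")))
  cat(sprintf("  state: %d %s coordinate(s); exact density: %s\n",
              x$state_dim, if (x$discrete) "discrete" else "continuous",
              if (is.null(x$density)) "no" else "yes"))
  invisible(x)
}

#' @rdname models
#' @export
binomial_model <- function(k = 100) {
  stopifnot(k >= 1)
  new_model(
    name = "binomial", d = 1L, state_dim = 1L, discrete = TRUE,
    param_names = "logit_p",
    simulate = function(theta, x_prev, t_prev, t_next) {
      theta <- as_theta_matrix(theta, 1L)
      matrix(rbinom(nrow(theta), size = k, prob = expit(theta[, 1])), ncol = 1)
    },
    density = function(x_next, x_prev, dt, theta) {
      theta <- as_theta_matrix(theta, 1L)
      dbinom(x_next[1], size = k, prob = expit(theta[, 1]))
    },
    default_theta = logit(0.6), default_x0 = NA_real_,
    default_times = as.numeric(1:10),
    default_prior = function() prior_normal(0, 3^2))
}

#' @rdname models
#' @export
cir_model <- function(a = 0.5, sigma = 0.15, method = c("exact", "euler"),
                      n_steps = 32L) {
  method <- match.arg(method)
  stopifnot(a > 0, sigma > 0, n_steps >= 1)
  # Transition X(t+dt) | X(t) = x is c^{-1}/2 times a noncentral chi-square:
  # 2c X(t+dt) ~ chisq(df = 4ab/sigma^2, ncp = 2c x e^{-a dt}),
  # c = 2a / (sigma^2 (1 - e^{-a dt})).
  cpar <- function(dt) 2 * a / (sigma^2 * (1 - exp(-a * dt)))
  sim_exact <- function(theta, x_prev, t_prev, t_next) {
    theta <- as_theta_matrix(theta, 1L)
    dt <- t_next - t_prev
    b <- exp(theta[, 1])
    cc <- cpar(dt)
    df <- 4 * a * b / sigma^2
    ncp <- 2 * cc * x_prev[1] * exp(-a * dt)
    matrix(rchisq(nrow(theta), df = df, ncp = ncp) / (2 * cc), ncol = 1)
  }
  sim_euler <- function(theta, x_prev, t_prev, t_next) {
    theta <- as_theta_matrix(theta, 1L)
    b <- exp(theta[, 1])
    h <- (t_next - t_prev) / n_steps
    x <- rep(x_prev[1], nrow(theta))
    for (s in seq_len(n_steps)) {
      x <- x + a * (b - x) * h +
        sigma * sqrt(pmax(x, 0)) * rnorm(length(x), sd = sqrt(h))
      x <- pmax(x, 0) # full truncation keeps the diffusion non-negative
    }
    matrix(x, ncol = 1)
  }
  new_model(
    name = "cir", d = 1L, state_dim = 1L, discrete = FALSE,
    param_names = "log_b",
    simulate = if (method == "exact") sim_exact else sim_euler,
    density = function(x_next, x_prev, dt, theta) {
      theta <- as_theta_matrix(theta, 1L)
      b <- exp(theta[, 1])
      cc <- cpar(dt)
      2 * cc * dchisq(2 * cc * x_next[1], df = 4 * a * b / sigma^2,
                      ncp = 2 * cc * x_prev[1] * exp(-a * dt))
    },
    cdf = function(x_next, x_prev, dt, theta) {
      theta <- as_theta_matrix(theta, 1L)
      b <- exp(theta[, 1])
      cc <- cpar(dt)
      pchisq(2 * cc * max(x_next[1], 0), df = 4 * a * b / sigma^2,
             ncp = 2 * cc * x_prev[1] * exp(-a * dt))
    },
    default_theta = log(1), default_x0 = 1,
    default_times = seq(0, 4.5, by = 0.5),
    default_prior = function() prior_uniform(-5, 2))
}

# Binomial-thinning (+) Poisson-immigration pmf, vectorised over parameter
# rows; support of the convolution sum is 0..min(x_prev, x_next).
inar1_pmf <- function(x_next, x_prev, alpha, beta_lambda) {
  jmax <- min(x_prev, x_next)
  out <- numeric(length(alpha))
  for (j in 0:jmax) {
    out <- out + dbinom(j, size = x_prev, prob = alpha) *
      dpois(x_next - j, lambda = beta_lambda)
  }
  out
}

#' @rdname models
#' @export
inar1_model <- function() {
  new_model(
    name = "inar1", d = 2L, state_dim = 1L, discrete = TRUE,
    param_names = c("logit_alpha", "log_lambda"),
    simulate = function(theta, x_prev, t_prev, t_next) {
      theta <- as_theta_matrix(theta, 2L)
      n <- nrow(theta)
      surv <- if (x_prev[1] > 0) {
        rbinom(n, size = x_prev[1], prob = expit(theta[, 1]))
      } else {
        integer(n)
      }
      matrix(surv + rpois(n, lambda = exp(theta[, 2])), ncol = 1)
    },
    density = function(x_next, x_prev, dt, theta) {
      theta <- as_theta_matrix(theta, 2L)
      inar1_pmf(x_next[1], x_prev[1], expit(theta[, 1]), exp(theta[, 2]))
    },
    default_theta = c(logit(0.7), log(1)), default_x0 = 10,
    default_times = as.numeric(1:100),
    default_prior = function() prior_normal(c(0, 0), diag(3^2, 2)))
}

#' @rdname models
#' @export
lv_model <- function() {
  new_model(
    name = "lotka_volterra", d = 3L, state_dim = 2L, discrete = TRUE,
    param_names = c("log_r1", "log_r2", "log_r3"),
    simulate = function(theta, x_prev, t_prev, t_next) {
      theta <- as_theta_matrix(theta, 3L)
      lv_ssa_batch(nrow(theta), as.integer(x_prev[1]), as.integer(x_prev[2]),
                   exp(theta[, 1]), exp(theta[, 2]), exp(theta[, 3]),
                   t_next - t_prev)
    },
    density = NULL,
    default_theta = log(c(1, 0.005, 0.6)), default_x0 = c(50, 100),
    default_times = as.numeric(0:29),
    default_prior = function() {
      prior_normal(c(log(0.7), log(0.005), log(0.3)), diag(0.5, 3))
    })
}

#' Simulate one transition of a Markov model
#'
#' Draws `x(t_next) | x(t_prev) = x_prev` under the model's transition law at
#' parameter `theta` (transformed scale). Reproducible given `seed`; when
#' `seed` is `NULL` the current RNG stream is used (this is what the rejection
#' sampler does internally).
#'
#' @param model a [`pwabc_model`][models].
#' @param x_prev previous state (vector of length `model$state_dim`).
#' @param t_prev,t_next observation times, `t_next > t_prev` (ignored by
#'   unit-lag models such as the binomial).
#' @param theta parameter vector (length `model$d`) or an `N x d` matrix for
#'   `N` independent draws at different parameter values.
#' @param seed optional integer seed.
#' @return An `N x state_dim` matrix of simulated states.
#' @export
simulate_transition <- function(model, x_prev, t_prev, t_next, theta,
                                seed = NULL) {
  stopifnot(inherits(model, "pwabc_model"))
  if (!is.null(seed)) set.seed(seed)
  if (!isTRUE(is.na(x_prev[1])) && model$discrete &&
      any(x_prev < 0)) {
    abort("discrete states must be non-negative")
  }
  model$simulate(as_theta_matrix(theta, model$d), x_prev, t_prev, t_next)
}

#' Exact transition density
#'
#' Evaluates \eqn{\pi(x_{next} | x_{prev}, \theta)} for models with a
#' tractable transition law (binomial, CIR, INAR(1)). Vectorised over rows of
#' `theta`. The Lotka--Volterra model has no tractable likelihood and errors.
#'
#' @inheritParams simulate_transition
#' @param x_next state at which to evaluate the density/pmf.
#' @param dt time increment between the two observations.
#' @return A numeric vector of densities, one per row of `theta`.
#' @export
transition_density <- function(model, x_next, x_prev, dt, theta) {
  stopifnot(inherits(model, "pwabc_model"))
  if (is.null(model$density)) {
    abort(sprintf("model '%s' has no tractable likelihood", model$name))
  }
  model$density(x_next, x_prev, dt, as_theta_matrix(theta, model$d))
}

#' Gillespie simulation of the Lotka--Volterra system
#'
#' Runs the stochastic simulation algorithm for the predator--prey network
#' with mass-action hazards \eqn{(r_1 Y_1, r_2 Y_1 Y_2, r_3 Y_2)} from state
#' `(y1, y2)` for a duration `t_end`, returning the final state. The
#' all-extinct state is absorbing.
#'
#' @param y1,y2 initial prey and predator counts (non-negative integers).
#' @param rates numeric vector `(r1, r2, r3)` of positive reaction rates.
#' @param t_end simulation horizon.
#' @param seed optional integer seed.
#' @return Integer vector `c(y1, y2)` at time `t_end`.
#' @export
gillespie_lv <- function(y1, y2, rates, t_end, seed = NULL) {
  stopifnot(y1 >= 0, y2 >= 0, length(rates) == 3, all(rates > 0), t_end >= 0)
  if (!is.null(seed)) set.seed(seed)
  drop(lv_ssa_batch(1L, as.integer(y1), as.integer(y2),
                    rates[1], rates[2], rates[3], t_end))
}

#' Generate a synthetic observation series
#'
#' Applies the model's transition simulator sequentially along `times`,
#' starting from `x0` (recorded as the state at `times[1]`). With all
#' arguments at their defaults this reproduces each model's reference study
#' design (see [models]).
#'
#' @inheritParams simulate_transition
#' @param x0 initial state, recorded as the first row.
#' @param times strictly increasing observation times (length >= 2).
#' @return A tibble with column `t` and state columns `x1`, ... (`x` for a
#'   univariate state), one row per observation.
#' @export
generate_series <- function(model, theta = model$default_theta,
                            x0 = model$default_x0,
                            times = model$default_times, seed = NULL) {
  stopifnot(inherits(model, "pwabc_model"), length(times) >= 2,
            all(diff(times) > 0))
  if (!is.null(seed)) set.seed(seed)
  u <- model$state_dim
  states <- matrix(NA_real_, length(times), u)
  x <- x0
  if (anyNA(x0)) {
    # unit-lag IID models have no meaningful initial state: draw it
    x <- drop(model$simulate(as_theta_matrix(theta, model$d),
                             x0, times[1] - 1, times[1]))
  }
  states[1, ] <- x
  for (i in 2:length(times)) {
    x <- drop(model$simulate(as_theta_matrix(theta, model$d),
                             x, times[i - 1], times[i]))
    states[i, ] <- x
  }
  nm <- if (u == 1) "x" else paste0("x", seq_len(u))
  out <- tibble::as_tibble(as.data.frame(states))
  names(out) <- nm
  if (model$discrete) out <- dplyr::mutate(out,
                                           dplyr::across(dplyr::everything(),
                                                         as.integer))
  dplyr::bind_cols(tibble::tibble(t = times), out)
}

#' Read and write observation series
#'
#' Observation series are plain CSV files with a header `t,x1[,x2,...]` (or
#' `t,x` for a univariate state). Integer state columns are preserved
#' exactly.
#'
#' @param path file path.
#' @param series a data frame as returned by [generate_series()].
#' @return `read_series()` returns a tibble; `write_series()` returns the
#'   input invisibly.
#' @export
read_series <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (names(out)[1] != "t") abort("series CSV must have a leading 't' column")
  out
}

#' @rdname read_series
#' @export
write_series <- function(series, path) {
  readr::write_csv(series, path)
  invisible(series)
}

# Extract the state matrix (n x u) and times from a series data frame.
series_states <- function(data) {
  stopifnot(is.data.frame(data), "t" %in% names(data), nrow(data) >= 2)
  as.matrix(data[, setdiff(names(data), "t"), drop = FALSE])
}

#' Transformed-scale helpers
#'
#' `logit()` and `expit()` map a probability to the real line and back; the
#' binomial and INAR(1) models carry their probability parameters on the
#' logit scale.
#'
#' @param p probability in (0, 1).
#' @param x real number.
#' @export
logit <- function(p) log(p) - log1p(-p)

#' @rdname logit
#' @export
expit <- function(x) 1 / (1 + exp(-x))
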