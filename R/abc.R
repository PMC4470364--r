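#' ABC settings
#'
#' Bundles the rejection-ABC tuning constants: tolerance `epsilon`, norm
#' order `p`, accepted sample size `m` per factor, the per-factor attempt cap
#' and the internal simulation batch size. `epsilon = 0` (exact match) is
#' only admissible for discrete state spaces; this is validated against the
#' model when sampling starts, because for continuous states the acceptance
#' probability would be zero.
#'
#' @param epsilon acceptance tolerance on the \eqn{L^p} distance between the
#'   simulated and observed next state; `0` means exact match.
#' @param m number of accepted draws per factor (>= 2).
#' @param p norm order in `[1, Inf]`.
#' @param max_attempts cap on prior draws per factor before failing loudly.
#' @param batch_size number of prior draws simulated per vectorised batch.
#' @param seed default master seed used by [pwabc_run()].
#' @return A list of class `abc_config`.
#' @export
abc_config <- function(epsilon, m, p = 2, max_attempts = 1e7,
                       batch_size = 1e4, seed = 1L) {
  stopifnot(epsilon >= 0, m >= 2, max_attempts >= m, batch_size >= 1)
  if (p < 1) abort("norm order p must be >= 1")
  structure(list(epsilon = epsilon, p = p, m = as.integer(m),
                 max_attempts = max_attempts,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "abc_config")
}

#' Lp distance between states
#'
#' \eqn{\|x - y\|_p} with `p` in `[1, Inf]`; the acceptance rule of the
#' rejection sampler depends on the simulated state only through this
#' distance.
#'
#' @param x,y numeric vectors of equal length.
#' @param p norm order (>= 1; `Inf` gives the max norm).
#' @return A non-negative scalar, zero iff `x == y`.
#' @export
lp_distance <- function(x, y, p = 2) {
  if (p < 1) abort("norm order p must be >= 1")
  stopifnot(length(x) == length(y))
  z <- abs(x - y)
  if (is.infinite(p)) max(z) else sum(z^p)^(1 / p)
}

# Row-wise Lp distance of matrix X (N x u) to the vector y.
lp_dist_rows <- function(X, y, p) {
  Z <- abs(sweep(X, 2, y))
  if (is.infinite(p)) {
    do.call(pmax, as.data.frame(Z))
  } else if (p == 1) {
    rowSums(Z)
  } else if (p == 2) {
    sqrt(rowSums(Z^2))
  } else {
    rowSums(Z^p)^(1 / p)
  }
}

check_epsilon_model <- function(config, model) {
  if (config$epsilon == 0 && !model$discrete) {
    abort(paste("epsilon = 0 has acceptance probability zero for a",
                "continuous state space; use a positive tolerance"))
  }
}

new_factor_sample <- function(index, draws, distances, attempts, config,
                              seed, x_prev, x_next, t_prev, t_next,
                              param_names) {
  colnames(draws) <- param_names
  structure(
    list(index = index, draws = draws, distances = distances,
         attempts = attempts, epsilon = config$epsilon, p = config$p,
         m = nrow(draws), seed = seed, x_prev = x_prev, x_next = x_next,
         t_prev = t_prev, t_next = t_next),
    class = "factor_sample")
}

#' @export
print.factor_sample <- function(x, ...) {
  cat(sprintf(
    "<ABC factor sample %d: m = %d accepted of M = %d attempts (%.3g%%)>\n",
    x$index, x$m, x$attempts, 100 * x$m / x$attempts))
  invisible(x)
}

#' @export
as_tibble.factor_sample <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$draws))
  dplyr::bind_cols(
    tibble::tibble(factor = x$index, draw = seq_len(nrow(out))),
    out, tibble::tibble(distance = x$distances))
}

#' Rejection-ABC sample for one transition factor
#'
#' Targets the factor \eqn{\varphi_i(\theta) \propto
#' \pi(x_i | x_{i-1}, \theta)\,\pi(\theta)} by (i) drawing \eqn{\theta^*}
#' from the prior, (ii) simulating \eqn{x_i^* | x_{i-1}, \theta^*}, and
#' (iii) accepting when \eqn{\|x_i^* - x_i\|_p \le \epsilon}. The summary
#' statistic is the identity. With `epsilon = 0` on a discrete state space
#' the accepted draws are exact draws from the factor. The total number of
#' prior draws consumed up to the `m`-th acceptance is recorded as
#' `attempts` (\eqn{M_i}), and each accepted draw's distance is stored so
#' that samples can later be reused by [top_up()].
#'
#' @param model a [`pwabc_model`][models].
#' @param prior a [`pwabc_prior`][priors].
#' @param x_prev,x_next observed states at the two ends of the transition.
#' @param t_prev,t_next their observation times.
#' @param config an [abc_config()].
#' @param seed integer seed for this factor's sampling stream.
#' @param index factor index label (2..n), used in messages and output.
#' @return A `factor_sample` object; use [tidy()] / `as_tibble()` for a
#'   per-draw tibble.
#' @export
sample_factor <- function(model, prior, x_prev, x_next, t_prev, t_next,
                          config, seed, index = 2L) {
  stopifnot(inherits(model, "pwabc_model"), inherits(prior, "pwabc_prior"),
            inherits(config, "abc_config"))
  if (prior$d != model$d) abort("prior dimension does not match model")
  check_epsilon_model(config, model)
  set.seed(seed)
  res <- reject_loop(model, prior, x_prev, x_next, t_prev, t_next,
                     config, needed = config$m, index = index)
  new_factor_sample(index, res$draws, res$distances, res$attempts, config,
                    seed, x_prev, x_next, t_prev, t_next, model$param_names)
}

# Core batched rejection loop; uses the current RNG stream. Returns the first
# `needed` acceptances and the attempt count up to the last of them.
reject_loop <- function(model, prior, x_prev, x_next, t_prev, t_next,
                        config, needed, index, attempts_offset = 0) {
  acc <- matrix(numeric(0), 0, model$d)
  dist_acc <- numeric(0)
  idx_acc <- numeric(0)
  attempts <- 0
  while (length(dist_acc) < needed) {
    if (attempts >= config$max_attempts) {
      abort(sprintf(
        "factor %d: %d acceptances after %g attempts (rate %.3g%%); raise epsilon or max_attempts",
        index, length(dist_acc), attempts + attempts_offset,
        100 * length(dist_acc) / attempts), class = "pwabc_max_attempts")
    }
    nb <- min(config$batch_size, config$max_attempts - attempts)
    th <- prior_sample(prior, nb)
    xs <- model$simulate(th, x_prev, t_prev, t_next)
    dd <- lp_dist_rows(xs, x_next, config$p)
    ok <- which(dd <= config$epsilon)
    if (length(ok)) {
      acc <- rbind(acc, th[ok, , drop = FALSE])
      dist_acc <- c(dist_acc, dd[ok])
      idx_acc <- c(idx_acc, attempts + ok)
    }
    attempts <- attempts + nb
  }
  keep <- seq_len(needed)
  list(draws = acc[keep, , drop = FALSE], distances = dist_acc[keep],
       attempts = idx_acc[needed])
}

#' Run piecewise ABC over a whole observation series
#'
#' Factorises the posterior of a discretely observed Markov model over its
#' `n - 1` consecutive observation pairs and draws an independent
#' rejection-ABC sample for every factor (the first-observation likelihood
#' \eqn{\pi(x_1|\theta)} is dropped). Factors are mutually independent;
#' each factor `i` uses a seed derived deterministically from `seed` via an
#' integer hash, so results are identical whatever the order in which
#' factors are processed or how the work is split across processes.
#'
#' @param data a data frame with a time column `t` and one column per state
#'   coordinate (as produced by [generate_series()] or [read_series()]).
#' @param model a [`pwabc_model`][models].
#' @param prior a [`pwabc_prior`][priors]; defaults to the model's reference
#'   prior.
#' @param config an [abc_config()].
#' @param seed master seed; per-factor seeds are derived from it.
#' @param progress print one line per completed factor.
#' @return An object of class `pwabc_fit` holding the per-factor samples and
#'   everything needed to recombine them; see [posterior_gaussian()],
#'   [posterior_kde()], [tidy.pwabc_fit()], [glance.pwabc_fit()].
#' @examples
#' mod <- binomial_model(k = 20)
#' dat <- generate_series(mod, times = 1:4, seed = 42)
#' fit <- pwabc_run(dat, mod, config = abc_config(epsilon = 0, m = 50))
#' glance(fit)
#' @export
pwabc_run <- function(data, model, prior = model$default_prior(),
                      config, seed = config$seed, progress = FALSE) {
  stopifnot(inherits(model, "pwabc_model"), inherits(config, "abc_config"))
  X <- series_states(data)
  if (ncol(X) != model$state_dim) {
    abort(sprintf("series has %d state column(s); model '%s' expects %d",
                  ncol(X), model$name, model$state_dim))
  }
  check_epsilon_model(config, model)
  times <- data$t
  n <- nrow(X)
  factors <- vector("list", n - 1)
  for (i in 2:n) {
    fs <- sample_factor(model, prior, X[i - 1, ], X[i, ],
                        times[i - 1], times[i], config,
                        seed = factor_seed(seed, i), index = i)
    factors[[i - 1]] <- fs
    if (progress) {
      message(sprintf("factor %d/%d: M = %d, acceptance %.3g%%",
                      i, n, fs$attempts, 100 * fs$m / fs$attempts))
    }
  }
  structure(list(factors = factors, model = model, prior = prior,
                 config = config, seed = seed, data = tibble::as_tibble(data)),
            class = "pwabc_fit")
}

#' @export
print.pwabc_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<pwabc fit: %s model, %d factors, m = %d, epsilon = %g>\n",
              x$model$name, g$n_factors, x$config$m, x$config$epsilon))
  cat(sprintf("  acceptance: %.3g%% (mean over factors), %.3g%% (pooled)\n",
              100 * g$accept_mean, 100 * g$accept_pooled))
  invisible(x)
}

#' Reuse an ABC sample under a smaller tolerance or larger sample size
#'
#' Because accepted draws are independent across and within factors, a
#' factor's sample can be reused after a retrospective decision to tighten
#' `epsilon` or enlarge `m`: draws whose recorded distance satisfies the new
#' tolerance are retained, and fresh draws are appended until `new_m`
#' acceptances. Attempt counts accumulate, so the acceptance-rate estimator
#' \eqn{\hat c_i} stays (asymptotically) unbiased.
#'
#' @param existing a `factor_sample` from [sample_factor()].
#' @param model,prior,config as in [sample_factor()]; `config` supplies the
#'   attempt cap and batch size.
#' @param new_epsilon new tolerance, `<= existing$epsilon` (default: keep).
#' @param new_m new accepted-sample size (default: keep).
#' @param seed seed for the fresh draws (only used if any are needed).
#' @return A new `factor_sample` with `new_m` accepted draws.
#' @export
top_up <- function(existing, model, prior, config,
                   new_epsilon = existing$epsilon, new_m = existing$m,
                   seed = existing$seed + 1L) {
  stopifnot(inherits(existing, "factor_sample"))
  if (new_epsilon > existing$epsilon && new_m < existing$m) {
    abort("top_up requires new_epsilon <= epsilon or new_m >= m")
  }
  cfg <- abc_config(epsilon = new_epsilon, m = max(2L, new_m), p = existing$p,
                    max_attempts = config$max_attempts,
                    batch_size = config$batch_size)
  keep <- existing$distances <= new_epsilon
  draws <- existing$draws[keep, , drop = FALSE]
  dists <- existing$distances[keep]
  attempts <- existing$attempts
  if (nrow(draws) >= new_m) {
    draws <- draws[seq_len(new_m), , drop = FALSE]
    dists <- dists[seq_len(new_m)]
  } else {
    set.seed(seed)
    res <- reject_loop(model, prior, existing$x_prev, existing$x_next,
                       existing$t_prev, existing$t_next, cfg,
                       needed = new_m - nrow(draws), index = existing$index,
                       attempts_offset = attempts)
    draws <- rbind(draws, res$draws)
    dists <- c(dists, res$distances)
    attempts <- attempts + res$attempts
  }
  new_factor_sample(existing$index, draws, dists, attempts, cfg, seed,
                    existing$x_prev, existing$x_next, existing$t_prev,
                    existing$t_next, colnames(existing$draws))
}

#' Tidy accessors for piecewise-ABC fits
#'
#' `tidy()` returns one row per factor with the attempt count and acceptance
#' rate; `glance()` returns a one-row summary including both conventions for
#' the average acceptance rate (the arithmetic mean over factors of
#' \eqn{m/M_i}, and the pooled rate \eqn{\sum m / \sum M_i}).
#'
#' @param x a `pwabc_fit`.
#' @param ... unused.
#' @export
tidy.pwabc_fit <- function(x, ...) {
  purrr::map_dfr(x$factors, function(f) {
    mu <- colMeans(f$draws)
    tibble::tibble(factor = f$index, m = f$m, attempts = f$attempts,
                   acceptance = f$m / f$attempts,
                   !!!setNames(as.list(mu), paste0("mean_", names(mu))))
  })
}

#' @rdname tidy.pwabc_fit
#' @export
glance.pwabc_fit <- function(x, ...) {
  rates <- purrr::map_dbl(x$factors, ~ .x$m / .x$attempts)
  total <- sum(purrr::map_dbl(x$factors, "attempts"))
  tibble::tibble(
    model = x$model$name, n_obs = nrow(x$data),
    n_factors = length(x$factors), m = x$config$m,
    epsilon = x$config$epsilon, p = x$config$p,
    accept_mean = mean(rates),
    accept_pooled = x$config$m * length(x$factors) / total,
    total_attempts = total)
}

#' @export
tidy.factor_sample <- function(x, ...) as_tibble.factor_sample(x)

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
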