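#' Exact posterior on a lattice
#'
#' For models with a tractable transition density (binomial, CIR, INAR(1)),
#' evaluates the exact factorised posterior
#' \eqn{\pi(\theta|x) \propto \pi(\theta)\prod_{i=2}^n
#' \pi(x_i|x_{i-1},\theta)} pointwise on a lattice (the first-observation
#' likelihood is dropped, matching the piecewise sampler), and the exact log
#' marginal likelihood as the log Riemann sum of likelihood times prior.
#' This is the reference the ABC machinery is validated against.
#'
#' @param model a [`pwabc_model`][models] with an exact transition density.
#' @param data observation series data frame (`t` plus state columns).
#' @param prior a [`pwabc_prior`][priors].
#' @param grid a [lattice_grid()] over the parameter space.
#' @return A list of class `exact_posterior`: `density` (a `grid_density`)
#'   and `log_marginal`.
#' @export
exact_posterior_grid <- function(model, data, prior, grid) {
  stopifnot(inherits(model, "pwabc_model"), inherits(grid, "lattice_grid"))
  if (is.null(model$density)) {
    abort(sprintf("model '%s' has no tractable likelihood", model$name))
  }
  X <- series_states(data)
  times <- data$t
  n <- nrow(X)
  G <- grid_points(grid)
  logg <- prior_logpdf(prior, G)
  fin <- is.finite(logg)
  for (i in 2:n) {
    dens <- model$density(X[i, ], X[i - 1, ], times[i] - times[i - 1],
                          G[fin, , drop = FALSE])
    logg[fin] <- logg[fin] + log(dens)
    fin <- is.finite(logg)
    if (!any(fin)) abort("grid mismatch: no posterior mass on the lattice",
                         class = "pwabc_grid_mismatch")
  }
  lm <- logsumexp(logg) + grid_cell_logvol(grid)
  structure(list(density = new_grid_density(grid, logg - lm, lm),
                 log_marginal = lm),
            class = "exact_posterior")
}

#' @export
print.exact_posterior <- function(x, ...) {
  cat("<exact lattice posterior>\n")
  print(x$density)
  cat(sprintf("  log marginal likelihood: %.6g\n", x$log_marginal))
  invisible(x)
}

# Implied single-transition ABC likelihood: the transition law convolved
# with the uniform epsilon-ball kernel, i.e. (1/V) * P(||X* - x_next||_p <=
# epsilon | x_prev, theta). Continuous univariate states use the model CDF
# when available, otherwise adaptive quadrature over [x - eps, x + eps];
# discrete states sum the pmf over the integer ball.
implied_factor_lik <- function(model, x_next, x_prev, dt, theta, epsilon, p) {
  V <- ball_normaliser(epsilon, p, model$state_dim, model$discrete)
  if (model$discrete) {
    r <- floor(epsilon)
    offs <- as.matrix(expand.grid(rep(list(seq(-r, r)), model$state_dim)))
    nrm <- if (is.infinite(p)) apply(abs(offs), 1, max) else
      rowSums(abs(offs)^p)^(1 / p)
    offs <- offs[nrm <= epsilon, , drop = FALSE]
    mass <- 0
    for (k in seq_len(nrow(offs))) {
      z <- x_next + offs[k, ]
      if (all(z >= 0)) mass <- mass + model$density(z, x_prev, dt, theta)
    }
    mass / V
  } else if (model$state_dim == 1 && !is.null(model$cdf)) {
    (model$cdf(x_next + epsilon, x_prev, dt, theta) -
       model$cdf(x_next - epsilon, x_prev, dt, theta)) / V
  } else if (model$state_dim == 1) {
    vapply(seq_len(nrow(theta)), function(k) {
      integrate(function(y) {
        vapply(y, function(yy) model$density(yy, x_prev, dt,
                                             theta[k, , drop = FALSE]), 0)
      }, lower = x_next - epsilon, upper = x_next + epsilon)$value / V
    }, 0)
  } else {
    abort("implied ABC likelihood needs a univariate continuous state or a discrete state space")
  }
}

#' Implied piecewise-ABC posterior on a lattice
#'
#' The distribution actually targeted by the piecewise sampler at tolerance
#' `epsilon`: each transition likelihood is replaced by its convolution with
#' the uniform \eqn{L^p}-ball kernel of radius `epsilon`, computed by
#' quadrature (a finite sum for discrete states), then combined with the
#' prior correction exactly as in [grid_posterior()]. At `epsilon = 0` on a
#' discrete state space this coincides with [exact_posterior_grid()]; as
#' `epsilon` shrinks it converges to the exact posterior, which is the
#' diagnostic this oracle exists for.
#'
#' @inheritParams exact_posterior_grid
#' @param epsilon ABC tolerance.
#' @param p norm order.
#' @return A list of class `exact_posterior` (density and the implied log
#'   marginal).
#' @export
implied_pwabc_posterior_grid <- function(model, data, prior, epsilon, p,
                                         grid) {
  stopifnot(inherits(model, "pwabc_model"), inherits(grid, "lattice_grid"))
  if (is.null(model$density)) {
    abort(sprintf("model '%s' has no tractable likelihood", model$name))
  }
  X <- series_states(data)
  times <- data$t
  n <- nrow(X)
  G <- grid_points(grid)
  logg <- prior_logpdf(prior, G)
  fin <- is.finite(logg)
  for (i in 2:n) {
    lik <- implied_factor_lik(model, X[i, ], X[i - 1, ],
                              times[i] - times[i - 1],
                              G[fin, , drop = FALSE], epsilon, p)
    logg[fin] <- logg[fin] + log(lik)
    fin <- is.finite(logg)
    if (!any(fin)) abort("grid mismatch: no posterior mass on the lattice",
                         class = "pwabc_grid_mismatch")
  }
  lm <- logsumexp(logg) + grid_cell_logvol(grid)
  structure(list(density = new_grid_density(grid, logg - lm, lm),
                 log_marginal = lm),
            class = "exact_posterior")
}

#' Distances between lattice densities
#'
#' Total-variation, sup-norm and Kullback--Leibler discrepancies between two
#' densities tabulated on the same lattice; used to quantify how the
#' piecewise-ABC posterior approaches the exact posterior.
#'
#' @param f,g `grid_density` objects on identical lattices (`f` is the
#'   reference for `kl`).
#' @return A tibble with columns `tv`, `sup`, `kl`.
#' @export
grid_distance <- function(f, g) {
  stopifnot(inherits(f, "grid_density"), inherits(g, "grid_density"))
  if (!isTRUE(all.equal(f$grid$axes, g$grid$axes))) {
    abort("densities must share the same lattice")
  }
  vol <- exp(grid_cell_logvol(f$grid))
  pf <- exp(f$log_density); pg <- exp(g$log_density)
  ok <- pf > 0
  tibble::tibble(
    tv = 0.5 * sum(abs(pf - pg)) * vol,
    sup = max(abs(pf - pg)),
    kl = sum(pf[ok] * (f$log_density[ok] - g$log_density[ok])) * vol)
}
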