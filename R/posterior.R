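#' Recombine piecewise-ABC factors into a posterior
#'
#' Two routes from a [pwabc_run()] fit to a posterior estimate and marginal
#' likelihood:
#'
#' * `posterior_gaussian()`: fit a Gaussian to each factor sample, take the
#'   closed-form product and prior correction. Fast and exact arithmetic,
#'   but inconsistent when factors are skewed.
#' * `posterior_kde()`: kernel density estimate per factor, combined in log
#'   space on a lattice. Consistent as `m` grows; limited to `d <= 3`.
#'
#' Both attach the marginal-likelihood estimate built from the per-factor
#' acceptance bookkeeping ([sum_log_c()]).
#'
#' @param fit a `pwabc_fit`.
#' @param q kernel bandwidth scale; default [default_q()] of the parameter
#'   dimension.
#' @param grid optional [lattice_grid()]; defaults to [grid_auto_bounds()]
#'   over the fitted factors.
#' @param k_sd,resolution forwarded to [grid_auto_bounds()] when `grid` is
#'   not supplied.
#' @return An object of class `pwabc_posterior` with elements `route`
#'   (`"gaussian"` or `"kde"`), `mean`, `cov`, `log_marginal`, and
#'   route-specific detail: `product` + `density` (a `gaussian_density`)
#'   for the Gaussian route; `density` (a `grid_density`) and `factors` for
#'   the kernel route.
#' @examples
#' mod <- binomial_model(k = 20)
#' dat <- generate_series(mod, times = 1:4, seed = 42)
#' fit <- pwabc_run(dat, mod, config = abc_config(epsilon = 0, m = 200))
#' posterior_gaussian(fit)
#' @export
posterior_gaussian <- function(fit) {
  stopifnot(inherits(fit, "pwabc_fit"))
  n <- nrow(fit$data)
  gf <- purrr::map(fit$factors, fit_gaussian_factor)
  prod_g <- product_of_gaussians(gf)
  dens <- gaussian_posterior(prod_g, fit$prior, n)
  lml <- log_marginal_gaussian(prod_g, fit$prior, n, sum_log_c(fit))
  structure(list(route = "gaussian", mean = dens$mean, cov = dens$cov,
                 log_marginal = lml, product = prod_g, density = dens,
                 factors = gf, param_names = fit$model$param_names),
            class = "pwabc_posterior")
}

#' @rdname posterior_gaussian
#' @export
posterior_kde <- function(fit, q = NULL, grid = NULL, k_sd = 6,
                          resolution = NULL) {
  stopifnot(inherits(fit, "pwabc_fit"))
  n <- nrow(fit$data)
  kf <- purrr::map(fit$factors, kde_factor, q = q)
  if (is.null(grid)) {
    grid <- grid_auto_bounds(kf, k_sd = k_sd, resolution = resolution,
                             prior = fit$prior)
  }
  dens <- grid_posterior(kf, fit$prior, grid, n)
  mom <- grid_moments(dens)
  lml <- sum_log_c(fit) + dens$log_norm
  structure(list(route = "kde", mean = mom$mean, cov = mom$cov,
                 log_marginal = lml, density = dens, factors = kf,
                 param_names = fit$model$param_names),
            class = "pwabc_posterior")
}

#' @export
print.pwabc_posterior <- function(x, ...) {
  cat(sprintf("<piecewise-ABC posterior (%s route)>\n", x$route))
  cat(sprintf("  mean: %s\n  sd:   %s\n  log marginal likelihood: %.6g\n",
              paste(signif(x$mean, 4), collapse = ", "),
              paste(signif(sqrt(diag(as.matrix(x$cov))), 4), collapse = ", "),
              x$log_marginal))
  invisible(x)
}

#' @export
tidy.pwabc_posterior <- function(x, ...) {
  tibble::tibble(term = x$param_names,
                 estimate = as.numeric(x$mean),
                 std.error = sqrt(diag(as.matrix(x$cov))))
}

#' @export
glance.pwabc_posterior <- function(x, ...) {
  tibble::tibble(route = x$route, d = length(x$mean),
                 log_marginal = x$log_marginal)
}

#' @export
autoplot.pwabc_posterior <- function(object, ...) {
  if (object$route == "kde") {
    autoplot(object$density, ...)
  } else {
    d <- length(object$mean)
    tb <- purrr::map_dfr(seq_len(d), function(j) {
      mu <- object$mean[j]; s <- sqrt(object$cov[j, j])
      th <- seq(mu - 4 * s, mu + 4 * s, length.out = 200)
      tibble::tibble(parameter = object$param_names[j], theta = th,
                     density = dnorm(th, mu, s))
    })
    ggplot2::ggplot(tb, ggplot2::aes(x = .data$theta, y = .data$density)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = expression(theta), y = "posterior density")
  }
}
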