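#' Kernel bandwidth defaults
#'
#' `default_q(d)` is the scalar \eqn{\{(d+2)/4\}^{-2/(d+4)}}, the choice of
#' proportionality constant for which the bandwidth
#' \eqn{H = q\,m^{-2/(d+4)}\,Q} is asymptotically optimal (minimum leading
#' MISE term) when the target density is Gaussian. `kde_bandwidth()` applies
#' the scaling to a sample covariance, so the kernel shape mimics the shape
#' of the sample. For products of many factors a larger `q` can be
#' preferable; a practical heuristic is to start around ten times the
#' default and reduce it until spurious wiggles appear in the density
#' estimate.
#'
#' @param d parameter dimension.
#' @param Q factor sample covariance (d x d, positive-definite).
#' @param m accepted sample size.
#' @param q bandwidth scale constant.
#' @return `default_q()` a positive scalar; `kde_bandwidth()` a d x d
#'   matrix.
#' @examples
#' default_q(2)  # exactly 1
#' kde_bandwidth(diag(2), m = 100, d = 2, q = default_q(2))
#' @export
default_q <- function(d) {
  stopifnot(d >= 1)
  ((d + 2) / 4)^(-2 / (d + 4))
}

#' @rdname default_q
#' @export
kde_bandwidth <- function(Q, m, d = nrow(Q), q = default_q(d)) {
  stopifnot(m >= 1, q > 0)
  Q <- as.matrix(Q)
  chol_pd(Q, "sample covariance Q")
  q * m^(-2 / (d + 4)) * Q
}

#' Kernel density estimate of one factor
#'
#' An m-component Gaussian mixture centred on the accepted draws, with a
#' common bandwidth matrix \eqn{H_i = q\,m^{-2/(d+4)}\,Q_i} proportional to
#' the sample covariance.
#'
#' @param samples a `factor_sample` or a matrix of draws (rows = draws).
#' @param q bandwidth scale; defaults to [default_q()] for the sample's
#'   dimension.
#' @return An object of class `kde_factor` with elements `points`, `H`, `q`,
#'   `m`.
#' @export
kde_factor <- function(samples, q = NULL) {
  draws <- if (inherits(samples, "factor_sample")) samples$draws
           else as.matrix(samples)
  m <- nrow(draws); d <- ncol(draws)
  if (m < 2) abort("kernel estimate needs at least 2 draws")
  if (is.null(q)) q <- default_q(d)
  H <- kde_bandwidth(cov(draws), m, d, q)
  structure(list(points = draws, H = H, q = q, m = m, d = d,
                 index = if (inherits(samples, "factor_sample")) samples$index else NA_integer_),
            class = "kde_factor")
}

#' @export
print.kde_factor <- function(x, ...) {
  cat(sprintf("<kernel factor: m = %d points, d = %d, q = %.4g>\n",
              x$m, x$d, x$q))
  invisible(x)
}

#' Log-density of a kernel factor
#'
#' Evaluates the m-term Gaussian-mixture log-density by log-sum-exp
#' (compiled), so products of a hundred factors can be tabulated on a fine
#' lattice without underflow.
#'
#' @param factor a [kde_factor()].
#' @param theta a parameter vector or `N x d` matrix of evaluation points.
#' @return A numeric vector of log-densities.
#' @export
kde_logpdf <- function(factor, theta) {
  stopifnot(inherits(factor, "kde_factor"))
  theta <- as_theta_matrix(theta, factor$d)
  prec <- inv_pd(factor$H, "bandwidth H")
  lconst <- -0.5 * factor$d * log(2 * pi) - 0.5 * logdet_pd(factor$H) -
    log(factor$m)
  gauss_mix_logpdf(factor$points, prec, lconst, theta)
}

# Log-density of a factor approximation (kernel or Gaussian) at grid points.
factor_logpdf <- function(factor, theta) {
  if (inherits(factor, "kde_factor")) {
    kde_logpdf(factor, theta)
  } else if (inherits(factor, "gaussian_factor")) {
    mvn_logpdf(theta, factor$mean, factor$cov)
  } else {
    abort("factors must be kde_factor or gaussian_factor objects")
  }
}

factor_moments <- function(factor) {
  if (inherits(factor, "kde_factor")) {
    list(mean = colMeans(factor$points), cov = cov(factor$points))
  } else {
    list(mean = factor$mean, cov = factor$cov)
  }
}

#' Evaluation lattices
#'
#' A lattice is a set of equally spaced knots per axis (at least 32 per
#' axis, at most three axes) on which log-densities are tabulated.
#' `grid_auto_bounds()` chooses per-axis ranges as the hull over factors of
#' `mean +/- k_sd * sd`, intersected with the prior's support box, with a
#' default resolution of 512 knots per axis for `d <= 2` and 128 for
#' `d = 3`.
#'
#' @param lower,upper per-axis bounds.
#' @param resolution knots per axis (scalar or per-axis vector).
#' @param factors list of fitted factor approximations ([kde_factor()] or
#'   [fit_gaussian_factor()] objects).
#' @param k_sd half-width of the per-factor range in factor standard
#'   deviations.
#' @param prior a [`pwabc_prior`][priors]; a uniform box clips the lattice.
#' @return An object of class `lattice_grid`.
#' @export
lattice_grid <- function(lower, upper, resolution = NULL) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  d <- length(lower)
  stopifnot(length(upper) == d, all(lower < upper))
  if (d > 3) {
    abort("lattice evaluation is limited to d <= 3; use the Gaussian route for higher-dimensional parameters")
  }
  if (is.null(resolution)) resolution <- if (d <= 2) 512L else 128L
  resolution <- rep_len(as.integer(resolution), d)
  if (any(resolution < 32)) abort("need at least 32 knots per axis")
  axes <- purrr::map(seq_len(d), ~ seq(lower[.x], upper[.x],
                                       length.out = resolution[.x]))
  structure(list(axes = axes, d = d,
                 step = purrr::map_dbl(axes, ~ .x[2] - .x[1])),
            class = "lattice_grid")
}

#' @rdname lattice_grid
#' @export
grid_auto_bounds <- function(factors, k_sd = 6, resolution = NULL,
                             prior = NULL) {
  if (inherits(factors, c("kde_factor", "gaussian_factor"))) {
    factors <- list(factors)
  }
  mom <- purrr::map(factors, factor_moments)
  lo <- purrr::reduce(purrr::map(mom, ~ .x$mean - k_sd * sqrt(diag(as.matrix(.x$cov)))), pmin)
  hi <- purrr::reduce(purrr::map(mom, ~ .x$mean + k_sd * sqrt(diag(as.matrix(.x$cov)))), pmax)
  if (!is.null(prior)) {
    sup <- prior_support(prior)
    lo <- pmax(lo, sup["lower", ])
    hi <- pmin(hi, sup["upper", ])
  }
  if (any(lo >= hi)) abort("factor range does not intersect the prior support")
  lattice_grid(lo, hi, resolution)
}

#' @export
print.lattice_grid <- function(x, ...) {
  cat(sprintf("<lattice grid, d = %d>\n", x$d))
  for (j in seq_len(x$d)) {
    ax <- x$axes[[j]]
    cat(sprintf("  axis %d: [%g, %g], %d knots (step %g)\n",
                j, min(ax), max(ax), length(ax), x$step[j]))
  }
  invisible(x)
}

# All lattice points as a G x d matrix (column-major expand.grid order).
grid_points <- function(grid) {
  as.matrix(expand.grid(grid$axes, KEEP.OUT.ATTRS = FALSE))
}

grid_cell_logvol <- function(grid) sum(log(grid$step))

new_grid_density <- function(grid, log_density, log_norm) {
  structure(list(grid = grid, log_density = log_density,
                 log_norm = log_norm),
            class = "grid_density")
}

#' Lattice posterior from factor approximations
#'
#' Tabulates \eqn{g(\theta) = \pi(\theta)^{2-n}\prod_i\hat\varphi_i(\theta)}
#' pointwise on the lattice, entirely in log space (avoiding underflow in
#' products of up to a hundred factors), and normalises by the Riemann sum.
#' Factors may be kernel estimates, Gaussian fits, or a mixture of both.
#' Lattice points outside a uniform prior's box get zero mass.
#'
#' @param factors list of [kde_factor()] / [fit_gaussian_factor()] objects.
#' @param prior a [`pwabc_prior`][priors].
#' @param grid a [lattice_grid()] covering the region where the factors are
#'   non-negligible (see [grid_auto_bounds()]).
#' @param n number of observations in the series (`length(factors) + 1`).
#' @return An object of class `grid_density`: the lattice, the normalised
#'   log-density at each lattice point, and the log Riemann sum of the raw
#'   `g` (used by [grid_log_marginal()]).
#' @export
grid_posterior <- function(factors, prior, grid, n = length(factors) + 1) {
  stopifnot(inherits(grid, "lattice_grid"), n >= 2)
  G <- grid_points(grid)
  lp <- prior_logpdf(prior, G)
  logg <- ifelse(is.finite(lp), (2 - n) * lp, -Inf)
  for (f in factors) {
    fin <- is.finite(logg)
    if (!any(fin)) break
    logg[fin] <- logg[fin] + factor_logpdf(f, G[fin, , drop = FALSE])
  }
  if (!any(is.finite(logg))) {
    abort("grid mismatch: the lattice carries no posterior mass; widen or reposition the grid",
          class = "pwabc_grid_mismatch")
  }
  log_norm <- logsumexp(logg) + grid_cell_logvol(grid)
  new_grid_density(grid, logg - log_norm, log_norm)
}

#' Lattice marginal likelihood
#'
#' Adds the summed per-factor log normalising constants to the log Riemann
#' sum of \eqn{(\prod_i\hat\varphi_i)\,\pi^{2-n}} over the lattice.
#'
#' @inheritParams grid_posterior
#' @param sum_log_c \eqn{\sum_i \log\hat c_i}; see [sum_log_c()].
#' @return The scalar log marginal likelihood estimate.
#' @export
grid_log_marginal <- function(factors, prior, grid,
                              n = length(factors) + 1, sum_log_c) {
  gp <- grid_posterior(factors, prior, grid, n)
  sum_log_c + gp$log_norm
}

#' @export
print.grid_density <- function(x, ...) {
  mom <- grid_moments(x)
  cat(sprintf("<lattice density, d = %d, %s knots>\n", x$grid$d,
              paste(lengths(x$grid$axes), collapse = " x ")))
  cat(sprintf("  mean: %s\n  sd:   %s\n",
              paste(signif(mom$mean, 4), collapse = ", "),
              paste(signif(sqrt(diag(mom$cov)), 4), collapse = ", ")))
  invisible(x)
}

#' Moments and draws from a lattice density
#'
#' `grid_moments()` returns the mean vector and covariance matrix by
#' Riemann-weighted sums. `grid_sample()` draws by selecting lattice cells
#' with probability proportional to their mass and jittering uniformly
#' within the cell.
#'
#' @param density a `grid_density` from [grid_posterior()].
#' @param size number of draws.
#' @param seed optional integer seed.
#' @return `grid_moments()`: list with `mean` and `cov`; `grid_sample()`:
#'   a `size x d` matrix.
#' @export
grid_moments <- function(density) {
  stopifnot(inherits(density, "grid_density"))
  G <- grid_points(density$grid)
  w <- exp(density$log_density + grid_cell_logvol(density$grid))
  w <- w / sum(w)
  mu <- drop(crossprod(w, G))
  Gc <- sweep(G, 2, mu)
  Sigma <- crossprod(Gc * w, Gc)
  list(mean = mu, cov = (Sigma + t(Sigma)) / 2)
}

#' @rdname grid_moments
#' @param probs quantile levels for `grid_quantiles()`.
#' @export
grid_quantiles <- function(density, probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  stopifnot(inherits(density, "grid_density"))
  purrr::map_dfr(seq_len(density$grid$d), function(j) {
    mg <- grid_marginal(density, j)
    cdf <- cumsum(mg$density) * density$grid$step[j]
    cdf <- cdf / cdf[length(cdf)]
    tibble::tibble(parameter = paste0("theta_", j),
                   prob = probs,
                   quantile = stats::approx(cdf, mg$theta, xout = probs,
                                            ties = "ordered", rule = 2)$y)
  })
}

#' @rdname grid_moments
#' @export
grid_sample <- function(density, size, seed = NULL) {
  stopifnot(inherits(density, "grid_density"), size >= 1)
  if (!is.null(seed)) set.seed(seed)
  G <- grid_points(density$grid)
  w <- exp(density$log_density)
  idx <- sample.int(nrow(G), size, replace = TRUE, prob = w)
  jit <- matrix(runif(size * density$grid$d, -0.5, 0.5), size) *
    rep(density$grid$step, each = size)
  out <- G[idx, , drop = FALSE] + jit
  colnames(out) <- names(grid_as_tibble_coords(density))[seq_len(density$grid$d)]
  out
}

grid_as_tibble_coords <- function(density) {
  G <- grid_points(density$grid)
  nm <- paste0("theta_", seq_len(ncol(G)))
  colnames(G) <- nm
  tibble::as_tibble(as.data.frame(G))
}

#' @export
as_tibble.grid_density <- function(x, ...) {
  dplyr::bind_cols(grid_as_tibble_coords(x),
                   tibble::tibble(log_density = x$log_density,
                                  density = exp(x$log_density)))
}

#' @export
tidy.grid_density <- function(x, ...) as_tibble.grid_density(x)

#' @export
glance.grid_density <- function(x, ...) {
  mom <- grid_moments(x)
  d <- x$grid$d
  out <- tibble::tibble(d = d, knots = prod(lengths(x$grid$axes)),
                        log_norm = x$log_norm)
  for (j in seq_len(d)) {
    out[[paste0("mean_", j)]] <- mom$mean[j]
    out[[paste0("sd_", j)]] <- sqrt(mom$cov[j, j])
  }
  out
}

# Marginal lattice density along one axis (sums mass over the others).
grid_marginal <- function(density, axis) {
  tb <- as_tibble.grid_density(density)
  ax <- paste0("theta_", axis)
  vol_other <- exp(grid_cell_logvol(density$grid)) / density$grid$step[axis]
  tb |>
    dplyr::group_by(.data[[ax]]) |>
    dplyr::summarise(density = sum(.data$density) * vol_other,
                     .groups = "drop") |>
    dplyr::rename(theta = dplyr::all_of(ax))
}

#' Plot a lattice density
#'
#' One-dimensional densities are drawn as a line, two-dimensional ones as
#' filled contours, and three-dimensional ones as per-axis marginal
#' densities in facets.
#'
#' @param object a `grid_density`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.grid_density <- function(object, ...) {
  d <- object$grid$d
  if (d == 1) {
    ggplot2::ggplot(as_tibble.grid_density(object),
                    ggplot2::aes(x = .data$theta_1, y = .data$density)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = expression(theta), y = "posterior density")
  } else if (d == 2) {
    ggplot2::ggplot(as_tibble.grid_density(object),
                    ggplot2::aes(x = .data$theta_1, y = .data$theta_2,
                                 z = .data$density)) +
      ggplot2::geom_contour_filled(show.legend = FALSE) +
      ggplot2::labs(x = expression(theta[1]), y = expression(theta[2]))
  } else {
    tb <- purrr::map_dfr(seq_len(d), function(j) {
      dplyr::mutate(grid_marginal(object, j),
                    parameter = paste0("theta_", j))
    })
    ggplot2::ggplot(tb, ggplot2::aes(x = .data$theta, y = .data$density)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = expression(theta), y = "marginal density")
  }
}
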