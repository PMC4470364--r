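# Kernel factor estimates and lattice machinery.

test_that("default_q evaluates the Gaussian-optimal constant", {
  expect_equal(default_q(2), 1)
  expect_equal(default_q(1), (3 / 4)^(-2 / 5), tolerance = 1e-12)
  expect_equal(default_q(1), 1.12195, tolerance = 1e-5)
  expect_equal(default_q(4), (3 / 2)^(-1 / 4), tolerance = 1e-12)
  expect_equal(default_q(4), 0.90360, tolerance = 1e-5)
})

test_that("kde_bandwidth scales the sample covariance correctly", {
  expect_equal(kde_bandwidth(matrix(1), m = 1, d = 1, q = 1), matrix(1))
  H <- kde_bandwidth(matrix(1), m = 10000, d = 1, q = 1.12195)
  expect_equal(H[1, 1], 1.12195 * 10000^(-0.4), tolerance = 1e-10)
  expect_equal(H[1, 1], 0.028183, tolerance = 1e-4)
  Q <- matrix(c(2, 0.5, 0.5, 1), 2)
  expect_equal(kde_bandwidth(2 * Q, m = 50, d = 2),
               2 * kde_bandwidth(Q, m = 50, d = 2))
  expect_error(kde_bandwidth(matrix(c(1, 2, 2, 1), 2), m = 10),
               "positive-definite")
})

test_that("kde_logpdf is an exact Gaussian mixture log-density", {
  # single kernel at 0 with unit bandwidth is a standard normal
  f1 <- structure(list(points = matrix(0), H = matrix(1), q = 1, m = 1L,
                       d = 1L), class = "kde_factor")
  th <- c(-2, 0, 1.7)
  expect_equal(kde_logpdf(f1, matrix(th)), dnorm(th, log = TRUE),
               tolerance = 1e-12)
  # naive direct-summation oracle at probe points, 2-D
  set.seed(5)
  pts <- matrix(rnorm(60), ncol = 2)
  kf <- kde_factor(pts)
  probes <- matrix(rnorm(10), ncol = 2)
  Hinv <- solve(kf$H)
  naive <- apply(probes, 1, function(p) {
    terms <- apply(pts, 1, function(x) {
      z <- p - x
      exp(-0.5 * drop(t(z) %*% Hinv %*% z)) /
        (2 * pi * sqrt(det(kf$H)))
    })
    log(mean(terms))
  })
  expect_equal(kde_logpdf(kf, probes), naive, tolerance = 1e-10)
  # normalisation on a wide lattice
  set.seed(6)
  kf1 <- kde_factor(matrix(rnorm(400), ncol = 1))
  th <- seq(-10, 10, length.out = 4001)
  riemann <- sum(exp(kde_logpdf(kf1, matrix(th)))) * (th[2] - th[1])
  expect_equal(riemann, 1, tolerance = 1e-4)
})

test_that("lattice construction validates its invariants", {
  g <- lattice_grid(c(-1, 0), c(1, 4), resolution = c(64, 128))
  expect_equal(lengths(g$axes), c(64L, 128L))
  expect_equal(g$step, c(2 / 63, 4 / 127))
  expect_error(lattice_grid(0, 1, resolution = 16), "32 knots")
  expect_error(lattice_grid(rep(0, 4), rep(1, 4)), "d <= 3")
})

test_that("grid_auto_bounds hulls factor ranges and clips to the prior box", {
  f <- structure(list(mean = 0, cov = matrix(1), m = 10L),
                 class = "gaussian_factor")
  g <- grid_auto_bounds(list(f), k_sd = 6, resolution = 64)
  expect_equal(range(g$axes[[1]]), c(-6, 6))
  gclip <- grid_auto_bounds(list(f), k_sd = 7, resolution = 64,
                            prior = prior_uniform(-5, 2))
  expect_equal(range(gclip$axes[[1]]), c(-5, 2))
  f2 <- structure(list(mean = 3, cov = matrix(0.25), m = 10L),
                  class = "gaussian_factor")
  ghull <- grid_auto_bounds(list(f, f2), k_sd = 2, resolution = 64)
  expect_equal(range(ghull$axes[[1]]), c(-2, 4))
  expect_error(grid_auto_bounds(list(f2), k_sd = 1, resolution = 64,
                                prior = prior_uniform(-5, 0)),
               "does not intersect")
})

test_that("grid_posterior normalises, matches the closed form, and is
           stable under lattice perturbations", {
  fs <- list(structure(list(mean = 0.5, cov = matrix(0.3), m = 10L),
                       class = "gaussian_factor"),
             structure(list(mean = 0.9, cov = matrix(0.5), m = 10L),
                       class = "gaussian_factor"))
  pri <- prior_normal(0, 4)
  grid <- lattice_grid(-4, 5, 512)
  gp <- grid_posterior(fs, pri, grid, n = 3)
  vol <- exp(pwabc:::grid_cell_logvol(grid))
  expect_equal(sum(exp(gp$log_density)) * vol, 1, tolerance = 1e-6)
  mom <- grid_moments(gp)
  closed <- gaussian_posterior(product_of_gaussians(fs), pri, n = 3)
  expect_equal(as.numeric(mom$mean), as.numeric(closed$mean),
               tolerance = 1e-4)
  expect_equal(mom$cov[1, 1], closed$cov[1, 1], tolerance = 1e-4)
  # single factor with a uniform prior is just the factor, renormalised
  g1 <- grid_posterior(fs[1], prior_uniform(-4, 5), lattice_grid(-4, 5, 256),
                       n = 2)
  m1 <- grid_moments(g1)
  expect_equal(as.numeric(m1$mean), 0.5, tolerance = 1e-3)
  # shifting the lattice by half a cell barely moves the mean
  step <- grid$step / 2
  gp_sh <- grid_posterior(fs, pri,
                          lattice_grid(-4 + step, 5 + step, 512), n = 3)
  expect_lt(abs(grid_moments(gp_sh)$mean - mom$mean), 1e-3)
  # doubling the resolution barely moves the mean
  gp_hi <- grid_posterior(fs, pri, lattice_grid(-4, 5, 1024), n = 3)
  expect_lt(abs(grid_moments(gp_hi)$mean - mom$mean), 1e-3)
  # a lattice entirely outside the prior's support errors loudly
  expect_error(grid_posterior(fs, prior_uniform(-4, 5),
                              lattice_grid(6, 8, 64), n = 3),
               "grid mismatch")
})

test_that("grid_log_marginal reduces to sum_log_c for one normalised factor
           and matches the Gaussian closed form", {
  f <- structure(list(mean = 0.2, cov = matrix(0.4), m = 10L),
                 class = "gaussian_factor")
  pri <- prior_normal(0, 4)
  grid <- lattice_grid(-6, 6, 1024)
  expect_equal(grid_log_marginal(list(f), pri, grid, n = 2, sum_log_c = -5.5),
               -5.5, tolerance = 1e-6)
  fs <- list(f, structure(list(mean = -0.3, cov = matrix(0.6), m = 10L),
                          class = "gaussian_factor"))
  lml_grid <- grid_log_marginal(fs, pri, grid, n = 3, sum_log_c = -2)
  lml_gauss <- log_marginal_gaussian(product_of_gaussians(fs), pri, n = 3,
                                     sum_log_c = -2)
  expect_equal(lml_grid, lml_gauss, tolerance = 1e-4)
})

test_that("grid_quantiles inverts the lattice CDF", {
  f <- structure(list(mean = 1, cov = matrix(4), m = 10L),
                 class = "gaussian_factor")
  gd <- grid_posterior(list(f), prior_uniform(-11, 13),
                       lattice_grid(-11, 13, 2048), n = 2)
  qs <- grid_quantiles(gd, probs = c(0.025, 0.5, 0.975))
  expect_equal(qs$quantile, qnorm(c(0.025, 0.5, 0.975), 1, 2),
               tolerance = 1e-2)
})

test_that("grid_sample draws from the tabulated density", {
  f <- structure(list(mean = 0, cov = matrix(1), m = 10L),
                 class = "gaussian_factor")
  gd <- grid_posterior(list(f), prior_uniform(-8, 8),
                       lattice_grid(-8, 8, 512), n = 2)
  x <- grid_sample(gd, 1e5, seed = 4)
  expect_equal(mean(x), 0, tolerance = 0.01)
  # ECDF against the lattice CDF
  vol <- exp(pwabc:::grid_cell_logvol(gd$grid))
  cdf <- cumsum(exp(gd$log_density)) * vol
  knots <- gd$grid$axes[[1]]
  expect_lt(max(abs(ecdf(x[, 1])(knots + gd$grid$step / 2) - cdf)), 0.01)
  # a grid collapsed to one active cell puts all draws there
  gd2 <- gd
  gd2$log_density <- rep(-Inf, length(gd$log_density))
  gd2$log_density[100] <- 0
  x2 <- grid_sample(gd2, 100, seed = 1)
  expect_true(all(abs(x2[, 1] - knots[100]) <= gd$grid$step / 2 + 1e-12))
})
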