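# Gaussian factor fits, the closed-form product, posterior and evidence.

gf <- function(mean, cov) {
  structure(list(mean = mean, cov = as.matrix(cov), m = 1000L),
            class = "gaussian_factor")
}

test_that("fit_gaussian_factor uses the unbiased moment estimators", {
  f <- fit_gaussian_factor(matrix(c(0, 2), ncol = 1))
  expect_equal(as.numeric(f$mean), 1)
  expect_equal(f$cov[1, 1], 2) # (m-1) denominator
  expect_error(fit_gaussian_factor(matrix(c(3, 3, 3), ncol = 1)),
               "positive-definite")
  expect_error(fit_gaussian_factor(matrix(1:2, 1)), "m > d")
  set.seed(88)
  S <- matrix(c(2, 0.7, 0.7, 1), 2)
  X <- pwabc:::mvn_sample(1e5, c(-1, 3), S)
  f2 <- fit_gaussian_factor(X)
  expect_equal(as.numeric(f2$mean), c(-1, 3),
               tolerance = 3 * sqrt(max(diag(S)) / 1e5) / 1)
  expect_lt(max(abs(f2$cov - S)), 0.05)
})

test_that("product of Gaussians: closed form, trivial cases, weight", {
  one <- product_of_gaussians(gf(0.7, 2.5))
  expect_equal(one$a, 0.7)
  expect_equal(one$B[1, 1], 2.5)
  expect_equal(one$log_w, 0)
  # two standard normals: B = 1/2, a = 0, w = integral of N(0,1)^2 = 1/(2 sqrt(pi))
  two <- product_of_gaussians(list(gf(0, 1), gf(0, 1)))
  expect_equal(two$B[1, 1], 0.5)
  expect_equal(two$a, 0)
  expect_equal(exp(two$log_w), 1 / (2 * sqrt(pi)), tolerance = 1e-12)
})

test_that("product weight agrees with quadrature of the density product", {
  fs <- list(gf(-1, 1), gf(0, 2), gf(2, 4))
  pr <- product_of_gaussians(fs)
  th <- seq(-30, 30, length.out = 2e5 + 1)
  prod_vals <- exp(dnorm(th, -1, 1, log = TRUE) +
                     dnorm(th, 0, sqrt(2), log = TRUE) +
                     dnorm(th, 2, 2, log = TRUE))
  w_quad <- sum((head(prod_vals, -1) + tail(prod_vals, -1)) / 2) *
    (th[2] - th[1])
  expect_equal(exp(pr$log_w), w_quad, tolerance = 1e-6)
})

test_that("pointwise product identity holds at random probes", {
  set.seed(12)
  for (d in 1:2) {
    fs <- lapply(1:5, function(i) {
      A <- matrix(rnorm(d * d), d)
      gf(rnorm(d), crossprod(A) + diag(d))
    })
    pr <- product_of_gaussians(fs)
    for (k in 1:5) {
      th <- rnorm(d, sd = 2)
      lhs <- sum(vapply(fs, function(f) pwabc:::mvn_logpdf(th, f$mean, f$cov), 0))
      rhs <- pr$log_w + pwabc:::mvn_logpdf(th, pr$a, pr$B)
      expect_equal(lhs, rhs, tolerance = 1e-10)
    }
  }
})

test_that("O(n) log-weight equals the pairwise double-product formula where
           the pairwise form is exact (scalar case, or a single pair)", {
  set.seed(23)
  for (n in c(2, 5, 8)) {
    fs <- lapply(seq_len(n), function(i) gf(rnorm(1, sd = 2),
                                            matrix(0.5 + runif(1), 1)))
    expect_equal(product_of_gaussians(fs)$log_w, log_weight_pairwise(fs),
                 tolerance = 1e-8)
  }
  fs2 <- lapply(1:2, function(i) {
    A <- matrix(rnorm(4), 2)
    gf(rnorm(2, sd = 2), crossprod(A) + 0.5 * diag(2))
  })
  expect_equal(product_of_gaussians(fs2)$log_w, log_weight_pairwise(fs2),
               tolerance = 1e-8)
})

test_that("Gaussian posterior: prior-correction limits and lattice oracle", {
  pr <- product_of_gaussians(list(gf(1, 0.5), gf(1.2, 0.7)))
  # n = 2: the (2 - n) term vanishes
  p2 <- gaussian_posterior(pr, prior_normal(0, 9), n = 2)
  expect_equal(p2$mean, pr$a)
  expect_equal(p2$cov, pr$B)
  # very diffuse prior: posterior tends to K(a, B)
  pflat <- gaussian_posterior(pr, prior_normal(0, 1e8), n = 5)
  expect_equal(pflat$mean, pr$a, tolerance = 1e-6)
  expect_equal(pflat$cov[1, 1], pr$B[1, 1], tolerance = 1e-6)
  # 1-D, n = 3: matches moments of the grid-normalised K(;a,B)/prior
  pr1 <- structure(list(a = 1, B = matrix(0.25, 1, 1), log_w = 0,
                        n_factors = 2), class = "gaussian_product")
  post <- gaussian_posterior(pr1, prior_normal(0, 9), n = 3)
  th <- seq(-6, 8, length.out = 2e5)
  lg <- dnorm(th, 1, 0.5, log = TRUE) - dnorm(th, 0, 3, log = TRUE)
  wts <- exp(lg - max(lg)); wts <- wts / sum(wts)
  expect_equal(as.numeric(post$mean), sum(wts * th), tolerance = 1e-6)
  expect_equal(post$cov[1, 1], sum(wts * (th - sum(wts * th))^2),
               tolerance = 1e-6)
  # wide B against a tight prior destroys positive-definiteness -> error
  wide <- structure(list(a = 0, B = matrix(4, 1, 1), log_w = 0,
                         n_factors = 3), class = "gaussian_product")
  expect_error(gaussian_posterior(wide, prior_normal(0, 1), n = 4),
               "lattice route")
})

test_that("Gaussian-route marginal likelihood matches quadrature", {
  pr1 <- structure(list(a = 1, B = matrix(0.25, 1, 1), log_w = -2.3,
                        n_factors = 2), class = "gaussian_product")
  # n = 2: the integral of a single normalised factor is exp(log_w)
  expect_equal(log_marginal_gaussian(pr1, prior_normal(0, 9), n = 2,
                                     sum_log_c = -1.7),
               -1.7 + (-2.3))
  # n = 3, Gaussian prior: quadrature of w K(theta;a,B) / prior
  th <- seq(-10, 12, length.out = 4e5)
  vals <- exp(-2.3 + dnorm(th, 1, 0.5, log = TRUE) -
                dnorm(th, 0, 3, log = TRUE))
  quad <- log(sum(vals) * (th[2] - th[1]))
  expect_equal(log_marginal_gaussian(pr1, prior_normal(0, 9), n = 3,
                                     sum_log_c = 0),
               quad, tolerance = 1e-6)
  # uniform prior: volume power times Gaussian mass over the box
  u <- prior_uniform(-5, 2)
  vals_u <- exp(-2.3 + dnorm(th, 1, 0.5, log = TRUE)) * (th >= -5 & th <= 2) *
    7^1 # pi(theta)^{2-n} = vol^{n-2} with n = 3
  quad_u <- log(sum(vals_u) * (th[2] - th[1]))
  # tolerance limited by the Riemann sum's error at the box edges
  expect_equal(log_marginal_gaussian(pr1, u, n = 3, sum_log_c = 0),
               quad_u, tolerance = 1e-5)
})

test_that("the Gaussian product can be far from the lattice posterior for
           skewed factors (documented failure mode)", {
  set.seed(3)
  # strongly skewed factor samples: exp-transformed normals
  draws1 <- matrix(exp(rnorm(4000, 0, 0.9)), ncol = 1)
  draws2 <- matrix(exp(rnorm(4000, 0.2, 0.9)), ncol = 1)
  pri <- prior_uniform(-2, 25)
  gfit <- list(fit_gaussian_factor(draws1), fit_gaussian_factor(draws2))
  kfit <- list(kde_factor(draws1), kde_factor(draws2))
  grid <- lattice_grid(-2, 25, 1024)
  pk <- grid_posterior(kfit, pri, grid, n = 3)
  pgauss <- product_of_gaussians(gfit)
  lg <- pwabc:::mvn_logpdf(pwabc:::grid_points(grid), pgauss$a, pgauss$B)
  gd <- pwabc:::new_grid_density(grid, lg - (pwabc:::logsumexp(lg) +
                                               log(grid$step)), 0)
  kl <- grid_distance(pk, gd)$kl
  expect_gt(kl, 0.05)
})
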