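# Per-factor rejection sampling, seeding contract, sample reuse.

test_that("lp_distance implements the Lp norms", {
  expect_equal(lp_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(lp_distance(c(3, 4), c(0, 0), p = 2), 5)
  expect_equal(lp_distance(c(3, 4), c(0, 0), p = 1), 7)
  expect_equal(lp_distance(c(3, 4), c(0, 0), p = Inf), 4)
  expect_error(lp_distance(1, 2, p = 0.5), "p must be >= 1")
})

test_that("constant-likelihood model accepts everything and returns prior draws", {
  mod <- constant_hit_model(target = 5)
  pri <- prior_normal(1, 4)
  fs <- sample_factor(mod, pri, x_prev = 5, x_next = 5, 0, 1,
                      abc_config(epsilon = 0, m = 3000), seed = 21)
  expect_equal(fs$attempts, fs$m) # acceptance rate 1
  expect_true(all(fs$distances == 0))
  ks <- stats::ks.test(fs$draws[, 1], pnorm, mean = 1, sd = 2)
  expect_gt(ks$p.value, 0.01)
})

test_that("epsilon = 0 with a continuous state space is rejected", {
  cm <- cir_model()
  expect_error(
    sample_factor(cm, cm$default_prior(), 1, 1.1, 0, 0.5,
                  abc_config(epsilon = 0, m = 10), seed = 1),
    "acceptance probability zero")
})

test_that("exact-match binomial factor reproduces the grid-quadrature factor", {
  mod <- binomial_model()
  pri <- prior_normal(0, 9)
  oracle <- binomial_factor_grid(x_obs = 60)
  fs <- sample_factor(mod, pri, x_prev = NA, x_next = 60, 0, 1,
                      abc_config(epsilon = 0, m = 5000, batch_size = 5e4),
                      seed = 17)
  sup <- ecdf_vs_grid_sup(fs$draws[, 1], oracle$theta, oracle$density,
                          oracle$step)
  expect_lt(sup, 0.02)
  # and the empirical acceptance rate estimates c_i (V = 1 at epsilon 0)
  expect_lt(abs(fs$m / fs$attempts - oracle$c_i),
            3 * sqrt(oracle$c_i * (1 - oracle$c_i) / fs$attempts))
})

test_that("accepted-sample ECDF converges to the exact factor as m grows", {
  mod <- binomial_model()
  pri <- prior_normal(0, 9)
  oracle <- binomial_factor_grid(x_obs = 55)
  sups <- vapply(c(500, 5000), function(m) {
    fs <- sample_factor(mod, pri, NA, 55, 0, 1,
                        abc_config(epsilon = 0, m = m, batch_size = 5e4),
                        seed = 101)
    ecdf_vs_grid_sup(fs$draws[, 1], oracle$theta, oracle$density, oracle$step)
  }, 0)
  expect_lt(sups[2], sups[1])
})

test_that("per-factor seeds make runs independent of processing order", {
  mod <- binomial_model()
  dat <- generate_series(mod, seed = 5)
  cfg <- abc_config(epsilon = 0, m = 100)
  fit <- pwabc_run(dat, mod, config = cfg, seed = 77)
  expect_length(fit$factors, 9)
  # re-running a single factor in isolation gives the identical sample
  i <- 6
  fs <- sample_factor(mod, mod$default_prior(), dat$x[i - 1], dat$x[i],
                      dat$t[i - 1], dat$t[i], cfg,
                      seed = pwabc:::factor_seed(77, i), index = i)
  expect_identical(fs$draws, fit$factors[[i - 1]]$draws)
  expect_identical(fs$attempts, fit$factors[[i - 1]]$attempts)
  # whole-run determinism
  fit2 <- pwabc_run(dat, mod, config = cfg, seed = 77)
  expect_identical(tidy(fit), tidy(fit2))
})

test_that("a two-observation series yields exactly one factor", {
  mod <- binomial_model()
  dat <- generate_series(mod, times = 1:2, seed = 1)
  fit <- pwabc_run(dat, mod, config = abc_config(epsilon = 0, m = 50),
                   seed = 1)
  expect_length(fit$factors, 1)
  expect_equal(fit$factors[[1]]$index, 2)
})

test_that("exhausting max_attempts fails loudly with factor and rate", {
  mod <- constant_hit_model(target = 5)
  pri <- prior_normal(0, 1)
  expect_error(
    sample_factor(mod, pri, 5, 99, 0, 1,
                  abc_config(epsilon = 0, m = 10, max_attempts = 500),
                  seed = 1, index = 4L),
    "factor 4.*raise epsilon")
})

test_that("top_up is a no-op at unchanged settings and filters exactly", {
  cm <- cir_model()
  pri <- cm$default_prior()
  cfg <- abc_config(epsilon = 0.05, m = 400, batch_size = 2e4)
  fs <- sample_factor(cm, pri, 1, 0.95, 0, 0.5, cfg, seed = 31)
  same <- top_up(fs, cm, pri, cfg)
  expect_identical(same$draws, fs$draws)
  expect_identical(same$attempts, fs$attempts)
  # halving epsilon retains exactly the brute-force filtered subset
  half <- top_up(fs, cm, pri, cfg, new_epsilon = 0.025)
  keep <- fs$distances <= 0.025
  expect_identical(half$draws[seq_len(sum(keep)), , drop = FALSE],
                   fs$draws[keep, , drop = FALSE])
  expect_equal(half$m, 400)
  expect_true(all(half$distances <= 0.025))
  expect_gt(half$attempts, fs$attempts)
  # asking only for a larger m keeps the whole original sample as a prefix
  more <- top_up(fs, cm, pri, cfg, new_m = 600)
  expect_identical(more$draws[1:400, , drop = FALSE], fs$draws)
  expect_equal(more$m, 600)
  # shrinking both epsilon and m is rejected
  expect_error(top_up(fs, cm, pri, cfg, new_epsilon = 0.1, new_m = 100),
               "new_epsilon <= epsilon or new_m >= m")
})

test_that("acceptance bookkeeping: distances all zero at exact match and
           both averaging conventions are reported", {
  fx <- binomial_fit_small()
  expect_true(all(vapply(fx$fit$factors,
                         function(f) all(f$distances == 0), TRUE)))
  g <- glance(fx$fit)
  rates <- vapply(fx$fit$factors, function(f) f$m / f$attempts, 0)
  expect_equal(g$accept_mean, mean(rates))
  expect_equal(g$accept_pooled,
               sum(vapply(fx$fit$factors, function(f) f$m, 0L)) /
                 sum(vapply(fx$fit$factors, function(f) f$attempts, 0)))
  tb <- tidy(fx$fit)
  expect_equal(nrow(tb), 9)
  expect_named(tb, c("factor", "m", "attempts", "acceptance", "mean_logit_p"))
})
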