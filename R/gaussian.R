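#' Gaussian approximation of a factor
#'
#' Fits a Gaussian \eqn{K(\theta; \bar\theta^*_i, Q_i)} to a factor's
#' accepted draws, with the unbiased sample mean and the
#' \eqn{(m-1)}-denominator sample covariance. As the sample grows this is
#' the Gaussian closest in Kullback--Leibler divergence to the factor it
#' approximates -- but no such optimality carries over to the *product* of
#' the fitted Gaussians, which is why the kernel route exists.
#'
#' @param samples a `factor_sample` from [sample_factor()], or a plain
#'   matrix/data frame of draws (one row per draw).
#' @return An object of class `gaussian_factor` with elements `mean`, `cov`
#'   and `m`.
#' @export
fit_gaussian_factor <- function(samples) {
  draws <- if (inherits(samples, "factor_sample")) samples$draws
           else as.matrix(samples)
  m <- nrow(draws); d <- ncol(draws)
  if (m <= d) abort(sprintf("need m > d draws to fit a covariance (m = %d, d = %d)", m, d))
  Q <- cov(draws)
  chol_pd(Q, "factor sample covariance") # rank-deficient sample errors here
  structure(list(mean = colMeans(draws), cov = Q, m = m,
                 index = if (inherits(samples, "factor_sample")) samples$index else NA_integer_),
            class = "gaussian_factor")
}

#' @export
print.gaussian_factor <- function(x, ...) {
  cat(sprintf("<Gaussian factor, d = %d, m = %d>\n  mean: %s\n",
              length(x$mean), x$m, paste(signif(x$mean, 4), collapse = ", ")))
  invisible(x)
}

#' Closed-form product of Gaussian factors
#'
#' The product of Gaussian densities is an unnormalised Gaussian,
#' \eqn{\prod_i K(\theta; \bar\theta^*_i, Q_i) = w\,K(\theta; a, B)} with
#' \eqn{B = (\sum_i Q_i^{-1})^{-1}}, \eqn{a = B \sum_i Q_i^{-1}
#' \bar\theta^*_i}. The log-weight is computed in log space through the
#' quadratic-form identity
#' \deqn{\log w = \tfrac12\log\det(2\pi B) - \sum_i \tfrac12\log\det(2\pi
#' Q_i) - \tfrac12\big(\sum_i \bar\theta_i^T Q_i^{-1}\bar\theta_i - a^T
#' B^{-1} a\big),}
#' which is mathematically identical to the pairwise double-product formula
#' but O(n) and stable for a hundred factors. The pairwise form is kept as
#' [log_weight_pairwise()] for cross-checking.
#'
#' @param factors a list of `gaussian_factor` objects (or a single one).
#' @return An object of class `gaussian_product` with elements `a`, `B`,
#'   `log_w` and `n_factors`.
#' @export
product_of_gaussians <- function(factors) {
  if (inherits(factors, "gaussian_factor")) factors <- list(factors)
  stopifnot(length(factors) >= 1)
  d <- length(factors[[1]]$mean)
  P <- matrix(0, d, d)     # running precision sum
  eta <- numeric(d)        # running precision-weighted mean sum
  q_sum <- 0               # sum of theta_i' Q_i^{-1} theta_i
  ld_sum <- 0              # sum of log det(2 pi Q_i)
  for (f in factors) {
    Qi_inv <- inv_pd(f$cov, "factor covariance Q_i")
    P <- P + Qi_inv
    eta <- eta + drop(Qi_inv %*% f$mean)
    q_sum <- q_sum + drop(t(f$mean) %*% Qi_inv %*% f$mean)
    ld_sum <- ld_sum + d * log(2 * pi) + logdet_pd(f$cov)
  }
  B <- inv_pd(P, "product precision")
  B <- (B + t(B)) / 2
  a <- drop(B %*% eta)
  log_w <- 0.5 * (d * log(2 * pi) + logdet_pd(B)) - 0.5 * ld_sum -
    0.5 * (q_sum - drop(t(a) %*% P %*% a))
  structure(list(a = a, B = B, log_w = log_w, n_factors = length(factors)),
            class = "gaussian_product")
}

#' @export
print.gaussian_product <- function(x, ...) {
  cat(sprintf("<Gaussian product of %d factors>\n  a: %s\n  log w: %.6g\n",
              x$n_factors, paste(signif(x$a, 4), collapse = ", "), x$log_w))
  invisible(x)
}

#' Pairwise log-weight of a Gaussian product
#'
#' The O(n^2) double-product formula for the product weight: for every
#' pair \eqn{s < t} the term
#' \eqn{\exp\{-\frac12(\bar\theta_s - \bar\theta_t)^T R_{st}
#' (\bar\theta_s - \bar\theta_t)\}} with \eqn{R_{st} = Q_s^{-1} B Q_t^{-1}},
#' times the determinant prefactors. Retained as an independent check of the
#' O(n) route in [product_of_gaussians()].
#'
#' Caution: this classical pairwise form is an exact identity only for
#' scalar parameters (`d = 1`, where the precision matrices commute) and
#' for a single pair (`n = 2`, where \eqn{R_{12} = (Q_1+Q_2)^{-1}}). For
#' matrix covariances with three or more factors the cross terms
#' \eqn{Q_s^{-1} B Q_t^{-1}} are non-symmetric and the double product is
#' no longer exact; the quadratic-form route, which satisfies the pointwise
#' identity \eqn{\prod_i K(\theta;\bar\theta_i,Q_i) = w K(\theta;a,B)} to
#' machine precision, is definitive.
#'
#' @inheritParams product_of_gaussians
#' @return The scalar `log_w`.
#' @export
log_weight_pairwise <- function(factors) {
  if (inherits(factors, "gaussian_factor")) factors <- list(factors)
  d <- length(factors[[1]]$mean)
  n <- length(factors)
  Qinv <- lapply(factors, function(f) inv_pd(f$cov))
  P <- Reduce(`+`, Qinv)
  B <- inv_pd(P)
  log_w <- 0.5 * (d * log(2 * pi) + logdet_pd(B)) -
    0.5 * sum(vapply(factors,
                     function(f) d * log(2 * pi) + logdet_pd(f$cov), 0))
  if (n >= 2) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      R_st <- Qinv[[s]] %*% B %*% Qinv[[t]]
      dm <- factors[[s]]$mean - factors[[t]]$mean
      log_w <- log_w - 0.5 * drop(t(dm) %*% R_st %*% dm)
    }
  }
  log_w
}

#' Closed-form Gaussian posterior
#'
#' Combines the Gaussian product \eqn{w K(\theta; a, B)} with the prior
#' correction \eqn{\pi(\theta)^{2-n}} of the factorised posterior. For a
#' Gaussian prior the posterior is Gaussian with
#' \deqn{\Sigma_{post} = ((2-n)\Sigma_{pri}^{-1} + B^{-1})^{-1}, \quad
#' \mu_{post} = \Sigma_{post}((2-n)\Sigma_{pri}^{-1}\mu_{pri} + B^{-1}a).}
#' For a uniform-box prior the correction is constant on the box, so the
#' untruncated `K(a, B)` moments are returned with the box recorded in the
#' `box` element. When the prior correction destroys positive-definiteness
#' (possible when `B` is wide relative to the prior and `n > 2`) an explicit
#' error recommends the lattice route.
#'
#' @param product a `gaussian_product`.
#' @param prior a [`pwabc_prior`][priors].
#' @param n the number of observations in the series (so `n - 1` factors).
#' @return An object of class `gaussian_density` with `mean`, `cov` and,
#'   for a uniform prior, `box`.
#' @export
gaussian_posterior <- function(product, prior, n) {
  stopifnot(inherits(product, "gaussian_product"), n >= 2)
  if (prior$kind == "uniform") {
    return(structure(list(mean = product$a, cov = product$B,
                          box = prior_support(prior)),
                     class = "gaussian_density"))
  }
  B_inv <- inv_pd(product$B, "product covariance B")
  prec <- (2 - n) * inv_pd(prior$cov, "prior covariance") + B_inv
  Sigma_post <- tryCatch(inv_pd(prec), error = function(e) NULL)
  if (is.null(Sigma_post)) {
    abort(paste("prior correction (2-n) destroys positive-definiteness of",
                "the posterior covariance; use the lattice route",
                "(grid_posterior) instead"), class = "pwabc_not_pd")
  }
  Sigma_post <- (Sigma_post + t(Sigma_post)) / 2
  mu_post <- drop(Sigma_post %*%
                    ((2 - n) * solve(prior$cov, prior$mean) + B_inv %*% product$a))
  structure(list(mean = mu_post, cov = Sigma_post, box = NULL),
            class = "gaussian_density")
}

#' @export
print.gaussian_density <- function(x, ...) {
  cat(sprintf("<Gaussian posterior, d = %d>\n  mean: %s\n  sd:   %s\n",
              length(x$mean), paste(signif(x$mean, 4), collapse = ", "),
              paste(signif(sqrt(diag(x$cov)), 4), collapse = ", ")))
  invisible(x)
}

# Gaussian mass of K(a, B) over a finite box. Exact for d = 1; for d in
# {2, 3} a Riemann sum on a lattice (mvtnorm-style box probabilities are not
# needed at higher accuracy anywhere in the package).
gaussian_box_mass_log <- function(a, B, box, resolution = 256L) {
  d <- length(a)
  lo <- box["lower", ]; hi <- box["upper", ]
  if (d == 1) {
    s <- sqrt(B[1, 1])
    return(unname(log(pnorm(hi, a, s) - pnorm(lo, a, s))))
  }
  if (d > 3) abort("box mass implemented for d <= 3")
  axes <- lapply(seq_len(d), function(j) {
    seq(lo[j], hi[j], length.out = resolution)
  })
  stepl <- sum(log(vapply(axes, function(ax) ax[2] - ax[1], 0)))
  G <- as.matrix(expand.grid(axes))
  logsumexp(mvn_logpdf(G, a, B)) + stepl
}

#' Log marginal likelihood, Gaussian route
#'
#' Estimates \eqn{\log\pi(x)} as \eqn{\sum_i \log\hat c_i + \log\int
#' (\prod_i\hat\varphi^g_i(\theta))\,\pi(\theta)^{2-n}\,d\theta}, the second
#' term in closed form for a Gaussian prior:
#' \deqn{w\,(\det B)^{-1/2}(\det\Sigma_{post})^{1/2}
#' \det(2\pi\Sigma_{pri})^{n/2-1}
#' \exp\{-\tfrac12(a-\mu_{pri})^T((2-n)^{-1}\Sigma_{pri}+B)^{-1}
#' (a-\mu_{pri})\}.}
#' For a uniform-box prior the correction is a constant power of the box
#' volume and the Gaussian mass over the box replaces the exponential term.
#'
#' @inheritParams gaussian_posterior
#' @param sum_log_c the sum of per-factor log normalising-constant estimates
#'   \eqn{\sum_i \log\hat c_i} (see [estimate_log_c()] and [sum_log_c()]).
#' @return The scalar log marginal likelihood estimate.
#' @export
log_marginal_gaussian <- function(product, prior, n, sum_log_c) {
  stopifnot(inherits(product, "gaussian_product"), n >= 2)
  a <- product$a; B <- product$B
  if (prior$kind == "uniform") {
    log_vol <- sum(log(prior$upper - prior$lower))
    return(sum_log_c + (n - 2) * log_vol + product$log_w +
             gaussian_box_mass_log(a, B, prior_support(prior)))
  }
  post <- gaussian_posterior(product, prior, n) # errors if not PD
  d <- length(a)
  log_int <- product$log_w +
    0.5 * (logdet_pd(post$cov) - logdet_pd(B)) +
    (n / 2 - 1) * (d * log(2 * pi) + logdet_pd(prior$cov))
  if (n > 2) {
    Mmat <- B + prior$cov / (2 - n)
    # (2-n)^{-1} Sigma_pri + B need not be PD (it is negative the other way);
    # the quadratic form is still the right analytic continuation, via solve.
    dm <- a - prior$mean
    log_int <- log_int - 0.5 * drop(t(dm) %*% solve(Mmat, dm))
  }
  sum_log_c + log_int
}
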