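#' Prior specifications
#'
#' Priors are placed directly on the transformed parameter \eqn{\theta}.
#' Two families are supported: a multivariate Gaussian
#' \eqn{N(\mu_{pri}, \Sigma_{pri})} and a uniform box (independent uniform
#' bounds per coordinate). The Gaussian prior admits the closed-form
#' posterior correction in the Gaussian product route; the uniform box is
#' treated as constant on its support.
#'
#' @param mean prior mean vector.
#' @param cov prior covariance matrix (a scalar is taken as a 1x1 variance;
#'   a vector as a diagonal).
#' @param lower,upper per-coordinate bounds, `lower < upper`.
#' @return An object of class `pwabc_prior`.
#' @examples
#' prior_normal(0, 3^2)
#' prior_uniform(-5, 2)
#' @name priors
NULL

#' @rdname priors
#' @export
prior_normal <- function(mean, cov) {
  mean <- as.numeric(mean)
  d <- length(mean)
  if (is.null(dim(cov))) {
    cov <- if (length(cov) == 1) diag(cov, d) else diag(as.numeric(cov))
  }
  cov <- as.matrix(cov)
  stopifnot(nrow(cov) == d, ncol(cov) == d)
  chol_pd(cov, "prior covariance")
  structure(list(kind = "gaussian", mean = mean, cov = cov, d = d),
            class = "pwabc_prior")
}

#' @rdname priors
#' @export
prior_uniform <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  stopifnot(length(lower) == length(upper), all(lower < upper))
  structure(list(kind = "uniform", lower = lower, upper = upper,
                 d = length(lower)),
            class = "pwabc_prior")
}

#' @export
print.pwabc_prior <- function(x, ...) {
  if (x$kind == "gaussian") {
    cat(sprintf("<Gaussian prior, d = %d>\n  mean: %s\n", x$d,
                paste(signif(x$mean, 4), collapse = ", ")))
  } else {
    cat(sprintf("<Uniform-box prior, d = %d>\n  box: %s\n", x$d,
                paste(sprintf("(%g, %g)", x$lower, x$upper), collapse = " x ")))
  }
  invisible(x)
}

#' Evaluate or sample a prior
#'
#' @param prior a [`pwabc_prior`][priors].
#' @param theta parameter vector or `N x d` matrix.
#' @param n number of draws.
#' @return `prior_logpdf()` a numeric vector of log-densities (`-Inf` outside
#'   a uniform box); `prior_sample()` an `n x d` matrix using the current RNG
#'   stream.
#' @export
prior_logpdf <- function(prior, theta) {
  stopifnot(inherits(prior, "pwabc_prior"))
  theta <- as_theta_matrix(theta, prior$d)
  if (prior$kind == "gaussian") {
    mvn_logpdf(theta, prior$mean, prior$cov)
  } else {
    inside <- colSums(t(theta) >= prior$lower & t(theta) <= prior$upper) ==
      prior$d
    ifelse(inside, -sum(log(prior$upper - prior$lower)), -Inf)
  }
}

#' @rdname prior_logpdf
#' @export
prior_sample <- function(prior, n) {
  stopifnot(inherits(prior, "pwabc_prior"))
  if (prior$kind == "gaussian") {
    mvn_sample(n, prior$mean, prior$cov)
  } else {
    d <- prior$d
    matrix(runif(n * d, rep(prior$lower, each = n), rep(prior$upper, each = n)),
           n, d)
  }
}

# Support box of a prior: matrix with rows lower/upper (-Inf/Inf if unbounded).
prior_support <- function(prior) {
  if (prior$kind == "uniform") {
    rbind(lower = prior$lower, upper = prior$upper)
  } else {
    rbind(lower = rep(-Inf, prior$d), upper = rep(Inf, prior$d))
  }
}
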