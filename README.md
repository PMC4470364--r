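# pwabc

Piecewise Approximate Bayesian Computation for discretely observed Markov
models.

## The problem

Stochastic models of population dynamics, chemical kinetics, count time
series or interest rates are often easy to *simulate* but have an
intractable likelihood, so conventional Bayesian inference is unavailable.
Rejection ABC replaces likelihood evaluation with simulation — accept a
prior draw $\theta^\ast$ when data simulated under it land within a
tolerance $\varepsilon$ of the observations — but for a whole time series
the acceptance rate forces summary statistics and large tolerances, both of
which bias the posterior.

For a Markov process observed at times $t_1 < \dots < t_n$ with states
$x_1, \dots, x_n$, the posterior factorises over consecutive observation
pairs:

$$
\pi(\theta \mid x) \propto \pi(\theta)^{2-n} \prod_{i=2}^{n}
\varphi_i(\theta), \qquad
\varphi_i(\theta) \propto \pi(x_i \mid x_{i-1}, \theta)\,\pi(\theta).
$$

Each factor involves a *single transition*, so rejection ABC per factor can
use the identity summary statistic and a tiny — for discrete state spaces,
zero — tolerance: simulate one step from the observed $x_{i-1}$ and accept
when $\lVert x_i^\ast - x_i \rVert_p \le \varepsilon$. The factors are
independent (embarrassingly parallel; samples reusable when $\varepsilon$
is tightened or $m$ increased). The accepted samples are recombined into a
full posterior by either

* a **Gaussian product**: fit $K(\theta;\bar\theta_i^\ast,Q_i)$ to each
  factor; the product is $w\,K(\theta;a,B)$ in closed form with
  $B=(\sum_i Q_i^{-1})^{-1}$, $a=B\sum_i Q_i^{-1}\bar\theta_i^\ast$ —
  fast, exact arithmetic, but inconsistent for skewed factors; or
* a **kernel density product**: bandwidth
  $H_i = q\,m^{-2/(d+4)}Q_i$ per factor, products evaluated in log space on
  a lattice — consistent as $m \to \infty$, limited to $d \le 3$.

Marginal likelihoods come for free from the sampler's bookkeeping:
$\hat c_i = m/(V M_i)$ with $M_i$ the attempts needed for $m$ acceptances
and $V$ the $L^p$-ball normaliser.

Four reference models are built in: IID binomial counts, the
Cox–Ingersoll–Ross diffusion (exact noncentral-$\chi^2$ transitions), the
INAR(1) count series (binomial thinning + Poisson immigration), and a
stochastic Lotka–Volterra predator–prey system (compiled Gillespie
simulator). The first three have tractable transition densities and serve
as exact oracles for validation.

## Worked example

Ten IID `Binomial(100, p)` counts with `p = 0.6`, inference on
`theta = logit(p)` under a `N(0, 3^2)` prior, exact-match rejection
(`epsilon = 0`) with `m = 5000` accepted draws per factor:

```r
library(pwabc)

mod <- binomial_model()                     # theta = logit(p), k = 100
dat <- generate_series(mod, seed = 42)      # n = 10 observations
fit <- pwabc_run(dat, mod, config = abc_config(epsilon = 0, m = 5000),
                 seed = 42)
fit
#> <pwabc fit: binomial model, 9 factors, m = 5000, epsilon = 0>
#>   acceptance: 0.55% (mean over factors), 0.549% (pooled)

tidy(posterior_gaussian(fit))
#> # A tibble: 1 x 3
#>   term    estimate std.error
#>   <chr>      <dbl>     <dbl>
#> 1 logit_p    0.348    0.0684

pk <- posterior_kde(fit)
tidy(pk)
#> # A tibble: 1 x 3
#>   term    estimate std.error
#>   <chr>      <dbl>     <dbl>
#> 1 logit_p    0.340    0.0696
```

Both routes put the posterior for `logit(p)` around 0.34–0.35 with
standard error 0.07, bracketing the generating value
`logit(0.6) = 0.4055` well within one standard deviation. The marginal
likelihood estimates agree with exact lattice quadrature of the same
posterior to a few hundredths:

```r
posterior_gaussian(fit)$log_marginal      # -30.67
pk$log_marginal                           # -30.71
exact_posterior_grid(mod, dat, mod$default_prior(),
                     pk$density$grid)$log_marginal   # -30.63
```

`autoplot(pk)` draws the lattice posterior; `glance(fit)` reports
per-factor acceptance bookkeeping; `top_up()` reuses stored samples under
a smaller tolerance or larger `m`. Whole-study runs driven by YAML
configurations (bundled under `inst/extdata/`) are available through
`run_pwabc()` or the `exec/pwabc` command-line wrapper, which write
samples, posterior grids, summaries and logs to an output directory.

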