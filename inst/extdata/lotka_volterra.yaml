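# Stochastic Lotka-Volterra study: rates (1, 0.005, 0.6), Y(0) = (50, 100),
# unit-spaced observations; inference on log-rates with Gaussian priors
# N(log 0.7, 0.5), N(log 0.005, 0.5), N(log 0.3, 0.5); exact-match
# rejection (epsilon = 0) and a heavier kernel smoothing q = 5.
# A full-length run (30 unit-spaced observations, m = 10000) is
# computationally demanding; this bundled configuration uses the scaled
# validation design: 10 observations at spacing 0.5 and m = 200.
model:
  name: lotka_volterra
data:
  generate:
    times:
      from: 0
      to: 4.5
      by: 0.5
    seed: 1
prior: default
abc:
  epsilon: 0
  m: 200
  max_attempts: 1.0e8
  batch_size: 100000
  seed: 1
approx: both
q: 5
out: runs/lotka_volterra
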