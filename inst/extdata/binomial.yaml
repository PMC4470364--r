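# Binomial toy study: n = 10 IID Binomial(100, 0.6) counts, inference on
# theta = logit(p) with a N(0, 3^2) prior, exact-match rejection sampling.
model:
  name: binomial
  params:
    k: 100
data:
  generate:
    seed: 1
prior: default
abc:
  epsilon: 0
  m: 5000
  seed: 1
approx: both
out: runs/binomial
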