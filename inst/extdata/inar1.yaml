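# INAR(1) study: n = 100 counts with (alpha, lambda) = (0.7, 1), X(0) = 10;
# inference on (logit(alpha), log(lambda)) with independent N(0, 3^2)
# priors, exact-match rejection sampling for all 99 factors.
model:
  name: inar1
data:
  generate:
    seed: 1
prior: default
abc:
  epsilon: 0
  m: 10000
  seed: 1
approx: both
out: runs/inar1
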