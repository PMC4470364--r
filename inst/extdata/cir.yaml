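# Cox-Ingersoll-Ross study: n = 10 equally spaced observations on [0, 4.5]
# with (a, b, sigma) = (0.5, 1, 0.15), X(0) = 1; inference on theta = log(b)
# with a Uniform(-5, 2) prior, tolerance 1e-2.
model:
  name: cir
  params:
    a: 0.5
    sigma: 0.15
data:
  generate:
    seed: 1
prior: default
abc:
  epsilon: 0.01
  m: 10000
  seed: 1
approx: both
out: runs/cir
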