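# Canonical benchmark configuration: equicorrelated two-class Gaussian
# traits with the mean shift solved so the full-feature Bayes accuracy is
# 0.99. Desk-scale protocol (10 repeats); set protocol.repeats: 100 for
# the benchmark-faithful run.
seed: 1
simulation:
  n1: 150
  n2: 150
  p: 25
  cov_family: compound_symmetry
  sigma: 1.0
  rho: 0.3
  epsilon_bayes: 0.99
ranking:
  C: 1.0
  step_size: 1
classifiers:
  - method: lda
  - method: svm_linear
    cost_grid: {base: 2, min_exp: 0, max_exp: 4}
protocol:
  k: 10
  repeats: 10
  stratified: true
  rank_mode: rank_inside_fold
fractions: [0.1, 0.2, 0.3, 0.4, 0.5, 1.0]
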