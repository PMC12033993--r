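# Study configuration for the analysis workflow (01_* .. 05_*).
# Every omitted field keeps the package default, which reproduces the
# standard dFNC settings: 26-TR Gaussian-tapered window (sigma 3 TR,
# TR 2 s), k = 3 city-block states with 5 replicates, minimum support
# 0.05, 80/20 split with 100 x 10-fold evaluation.
seed: 1
k: 3
k_range: [2, 3, 4, 5, 6]
distance: cityblock
n_replicates: 5
dichotomy: [HC, PD]
window:
  width_tr: 26
  step_tr: 1
  taper_sigma_tr: 3
  estimator: pearson
mining:
  min_support: 0.05
  min_length: 2
  max_length: 10
  compress_runs: true
protocol:
  train_fraction: 0.8
  cv_repeats: 100
  cv_folds: 10
  seed: 1
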