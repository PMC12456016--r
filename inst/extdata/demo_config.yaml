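## Demonstration configuration: a small corner of the full factorial design
## (the full study grid is 5 x 5 x 5 community cells with contamination
## levels {0, 1, 5, 10, 100} in two modes).
grid:
  n_per_group: [10, 30]
  n_taxa: [10, 100]
  sigma2: [0.1, 10]
  contam_levels: [0, 5, 100]
  contam_modes: [unweighted, weighted]
model:
  intercept_mean: 2.0
  intercept_sd: 2.0
  dispersion: 0.5
contamination:
  max_count: 100
  bias_ratio: 3.0
n_replicates: 2
master_seed: 1234
n_permutations: 999
alpha: 0.05
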