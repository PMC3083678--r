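# Full benchmark protocol: five parameter combinations x 25 replicates x
# six export time points, scored with both internal edge-detection methods.
# External Bayesian-clustering memberships can be scored alongside by
# pointing `external:` at a directory of <combo>_gen<g>_rep<r>.csv files.
seed: 1
replicates: 25
combos:
  - d1-mu1e4
  - d1-mu2.5e5
  - d11-mu1e4
  - d11-mu2.5e5
  - d11-mu1e4-b03
methods:
  monmonier:
    n_barriers: 4
    distance: residual
  wombling:
    grid_nx: 100
    grid_ny: 100
    bandwidth: 7
    percentile: 0.3
    alpha: 0.05
scoring:
  tolerance: 5
  coverage: 0.8
  min_edges: 5
output: benchmark_out
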