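# Scaled-down smoke benchmark: one small landscape, two replicates, two
# time points.  Finishes in a couple of minutes; useful for pipeline
# checks, not for method comparison.
seed: 7
replicates: 2
combos:
  - name: quick
    grid_width: 20
    grid_height: 20
    n_loci: 5
    mu: 0.002
    delta: 2
    burn_in_generations: 400
    export_generations: [0, 100]
    sample_size: 50
methods:
  monmonier:
    n_barriers: 2
  wombling:
    grid_nx: 20
    grid_ny: 20
    bandwidth: 3
scoring:
  tolerance: 2
  min_edges: 3
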