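# Demonstration run: one synthetic PD-pRBD cohort, male-vs-female contrast
# on the fractal-dimension network with the designed regional divergence in
# the male cell, plus a clinical correlation pass.
simulate:
  n_per_cell: 10
  groups: PD-pRBD
  sexes: [M, F]
  n_regions: 10
  vertices_per_region: [30, 45]
  metrics: FD
  effects:
    - {group: PD-pRBD, sex: M, regions: 1, metric: FD, shift: 12}
    - {group: PD-pRBD, sex: M, regions: 2, metric: FD, shift: -12}
    - {group: PD-pRBD, sex: M, regions: 3, metric: FD, shift: 18}
    - {group: PD-pRBD, sex: M, regions: 4, metric: FD, shift: -18}
sparsity: {from: 0.103, to: 0.4, by: 0.04}
mode: binary
n_null: 0
n_perm: 1000
grid_size: 128
covariates: [age, education, LEDD]
contrasts:
  - {group: PD-pRBD, between: sex, a: M, b: F}
correlations:
  - {score: HVLT_DR}
seed: 1
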