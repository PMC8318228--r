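params:
  J_TE: 2.5
  J_EPI: 2.5
  rho: 1.0
  lambda_med: 2.0
  lambda_chi: 2.0
  dt: 0.005
  force_cap_mult: 10.0
  adhesion_cutoff: 0.2
  max_links: 1.0
  refresh_every: 10.0
cell:
  R: 0.5
  h: 2.0
  n_vertices: 34.0
  d: 0.5
  R_lum: 0.25
scenario:
  kind: implantation
  te_rows: 5.0
  te_cols: 5.0
  rosette_grid: 3.0
  rosette_layers: 2.0
metrics:
  sample_every: 500.0
output:
  dir: epimech-out-implantation
  format: vtk
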