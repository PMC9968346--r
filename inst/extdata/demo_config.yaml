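# Demo configuration for run_pipeline(); all omitted entries take the
# package defaults (see default_config()).
seed: 42
landscape:
  n_rows: 20
  n_cols: 24
  n_env: 3
  warming_amplitude: 3
  cell_size_km: 10
genotypes:
  n_pops: 20
  n_haplotypes: 16
  l_neutral: 400
  l_adaptive: 80
  beta: 5
  drift_scale: 0.005
psi:
  n_perm: 999
gf:
  n_trees: 60
  n_bins: 150
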