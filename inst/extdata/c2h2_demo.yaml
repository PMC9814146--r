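# Demo retrieval run: acetylene, small problem sizes so the full pipeline
# finishes in about a minute on a laptop CPU.
molecule:
  scheme: c2h2
  equilibrium_labels: [1.20, 1.06]
database:
  mode: parameter-grid
  sampling: uniform
  count: 400
  parameters:
    R_CC: {min: 1.00, max: 1.40}
    R_CH: {min: 0.86, max: 1.26}
  seed: 11
grid: {e_min: 50, e_max: 300, n_energy: 16, a_min: 30, a_max: 180, n_angle: 16}
model: screened-born
prep:
  fractions: [0.8, 0.1, 0.1]
  split_seed: 5
cnn:
  conv_layers: [[8, 3], [8, 3]]
  fc_depth: 2
  fc_width: 32
  batch_size: 64
  learning_rate: 0.002
  epochs: 30
  batch_norm: true
  optimizer: adam
ensemble: {k: 2}
experiment:
  truth_labels: [1.23, 1.08]
  total_counts: 1.0e+7
  noise_seed: 3
  tolerances: 0.05
output_dir: c2h2_demo_out
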