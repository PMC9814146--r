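# Demo retrieval run: carbon disulfide with polar (R_CS, theta_SCS) labels,
# recovering a strongly bent geometry from a noisy synthetic measurement.
molecule:
  scheme: cs2
  equilibrium_labels: [1.55, 180]
database:
  mode: parameter-grid
  sampling: uniform
  count: 900
  parameters:
    R_CS: {min: 1.35, max: 2.15}
    theta_SCS: {min: 90, max: 180}
  seed: 31
grid: {e_min: 50, e_max: 300, n_energy: 24, a_min: 30, a_max: 180, n_angle: 24}
model: screened-born
prep:
  fractions: [0.8, 0.1, 0.1]
  split_seed: 5
cnn:
  conv_layers: [[8, 3], [8, 3]]
  fc_depth: 2
  fc_width: 48
  batch_size: 64
  learning_rate: 0.002
  epochs: 50
  batch_norm: true
  optimizer: adam
ensemble: {k: 2}
experiment:
  truth_labels: [1.87, 104.7]
  total_counts: 1.0e+7
  noise_seed: 3
  tolerances: [0.08, 5]
output_dir: cs2_demo_out
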