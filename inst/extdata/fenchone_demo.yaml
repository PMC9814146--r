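# Demo retrieval run for the 27-atom fenchone example: group-deformation
# database over four rigid atom groups plus a molecule-wide scale, labels =
# Cartesian coordinates of seven tracked atoms. Sizes are kept small for a
# quick demonstration; see the methods vignette for realistic settings.
molecule:
  scheme: cartesian
  xyz: fenchone_c10h16o_synthetic.xyz
  tracked_atoms: [2, 4, 5, 7, 8, 10, 11]
database:
  mode: group-deformation
  count: 600
  groups:
    - [10, 11]
    - [1, 2, 3, 12, 13, 14, 15, 16, 17]
    - [7, 8, 9, 23, 24, 25, 26, 27]
    - [4, 5, 6, 18, 19, 20, 21, 22]
  shift_range: [-0.3, 0.3]
  global_scale: [0.9, 1.1]
  seed: 21
grid: {e_min: 50, e_max: 300, n_energy: 16, a_min: 30, a_max: 180, n_angle: 16}
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
  epochs: 40
  batch_norm: true
  optimizer: adam
ensemble: {k: 2}
experiment:
  total_counts: 1.0e+7
  noise_seed: 3
  tolerances: 0.1
output_dir: fenchone_demo_out
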