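# dcsnet

Molecular structure retrieval from electron-diffraction cross-section maps
with a convolutional neural network.

## What this solves, and for whom

Laser-induced electron diffraction (LIED) images a gas-phase molecule with
its own rescattered electron wavepacket: after kinematic reduction, the
measurement is a 2D elastic differential cross-section (DCS) map over the
electron's return energy E_r and rescattering angle θ_r. Recovering atomic
coordinates from that image is a hard inverse problem — brute-force
matching against precalculated structures scales as n × 3^N for an N-atom
molecule at n steps per degree of freedom (about 1.45 × 10⁹ hours for
N = 20, n = 5 at five minutes per map).

`dcsnet` is for researchers in ultrafast electron diffraction and
strong-field physics who want a self-contained, reproducible pipeline
that

1. simulates 2D-DCS maps with the independent atomic model (IAM),
2. builds structure databases by parameter grids or rigid atom-group
   deformations plus a molecule-wide scale,
3. trains a CNN regressor from equilibrium-difference maps to structure
   label vectors, and
4. propagates Poisson counting noise into per-coordinate error bars.

## The model in brief

Orientation-averaged IAM cross-section at momentum transfer
q = 2k·sin(θ_r/2), k = √(2E_r) (atomic units):

    σ_tot(q) = Σ_i f_i²  +  Σ_{i≠j} f_i f_j · sin(qR_ij)/(qR_ij)
               └─ σ_atom ─┘  └────────── σ_coherent ──────────┘

with screened-Born amplitudes f(Z, q) = 2Z/(q² + α_Z²),
α_Z = Z^(1/3)/0.88534 bohr⁻¹ (a pluggable provider). The CNN (three
convolution blocks — 32@5×5, 32@3×3, 32@3×3 with batch normalization and
2×2 max-pooling — plus a fully connected stack; batch size 120) is trained
on sum-normalized maps minus the normalized equilibrium map, minimizing
the quadratic cost ½(y_pre − y_real)² by gradient descent
ω ← ω − α·∂Cost/∂ω. Retrieval uncertainty = per-dimension test MAE of a
retrained-model ensemble (model error) plus the prediction spread under
the counts ± √counts extrema of the measurement (experimental error).

See the methods vignette (`vignettes/dcsnet-methods.Rmd`) for assumptions,
defaults, and known limitations.

## Worked example

The packaged demo retrieves an acetylene structure from a synthetic noisy
measurement (400-structure database, 16×16 maps, two-model ensemble —
deliberately small; it runs in about a minute):

```r
library(dcsnet)
cfg <- read_run_config(system.file("extdata", "c2h2_demo.yaml",
                                   package = "dcsnet"))
cfg$output_dir <- "c2h2_demo_out"
report <- run_synthetic_experiment(cfg)
print(report)
#> <recovery_report> PASS
#>  label truth predicted  abs_error tolerance pass
#>   R_CC  1.23  1.206719 0.02328072      0.05 TRUE
#>   R_CH  1.08  1.113263 0.03326257      0.05 TRUE
print(report$run$correlation)
#> <correlation_report> r = 1.0000, 90% CI [1.0000, 1.0000] (B = 1000)
```

A hidden truth structure (C–C 1.23 Å, C–H 1.08 Å) was turned into an IAM
map, Poisson-noised at 10⁷ counts, and fed to the trained ensemble. The
ensemble's mean prediction lands within 0.04 Å of the truth even at this
miniature training scale, and the map recomputed from the prediction is
essentially perfectly correlated with the noisy input. Artifacts
(`prediction.json`, `train_report.csv`, `correlation.json`,
`manifest.json`) land in the output directory; at realistic scale the
same pipeline is driven by the bundled fenchone config
(`fenchone_demo.yaml`) or the `exec/dcsnet` command line
(`build-db`, `simulate`, `train`, `retrieve`, `synthetic-exp`,
`estimate-scaling`).

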