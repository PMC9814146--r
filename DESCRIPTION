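Package: dcsnet
Title: Molecular Structure Retrieval from Electron Diffraction Cross-Section
    Maps with Convolutional Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates two-dimensional elastic electron-scattering
    differential cross-section (DCS) maps for gas-phase molecules with the
    independent atomic model and inverts them with a convolutional neural
    network regressor to recover three-dimensional atomic coordinates, as
    used in laser-induced electron diffraction (LIED) imaging. Provides
    structure-database generators (parameter grids and rigid atom-group
    deformations with a global scale), equilibrium-difference map
    preparation, a self-contained CNN with batch normalization trained by
    gradient descent, Poisson counting-noise error propagation, Pearson
    correlation with bootstrap confidence intervals, and an end-to-end
    configuration-driven retrieval workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
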