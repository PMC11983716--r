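Package: msldyn
Title: Desk-Scale Multisite Lambda-Dynamics for Sequence Binding Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for multisite lambda-dynamics on
    reduced model Hamiltonians. Implements the composite alchemical potential
    with softmax implicit constraints, Langevin (BAOAB) sampling of the lambda
    coordinates, adaptive landscape flattening (ALF) of the alchemical free
    energy surface, three base-pair perturbation schemes for DNA sequence
    mutations (single lambda per pair, two lambdas per pair, and two lambdas
    with a quadratic inter-site coupling bias), endstate binning with a lambda
    cutoff, transition counting, population-based free energy estimation with
    block-bootstrap uncertainties, and thermodynamic-cycle assembly of relative
    binding free energies. Ships a synthetic toy-system generator emulating
    transcription-factor/DNA binding specificity (W-box style sequence wells in
    bound and unbound ensembles) together with an exact quadrature oracle for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
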