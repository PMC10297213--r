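Package: morphoRD
Title: Coupled Reaction-Diffusion and Cell Morphodynamics with Edge-Velocity
    Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates cell membrane ruffling by coupling mass-conserved
    reaction-diffusion (MCRD) models of Rho-GTPase signaling (Rac1, Cdc42,
    their inhibitors and upstream effectors) to a stochastic pixel-grid
    morphodynamic engine in which protrusion and retraction probabilities
    are modulated by local curvature, cell volume and actin-polymerization
    signaling. Provides a registry of single- and multi-GTPase reaction
    systems, phase-space classification of their dynamical regimes
    (Turing-unstable, excitable, oscillatory), and an image-analysis
    pipeline that extracts cell-edge velocity and near-edge biosensor
    signal from time-lapse mask/intensity stacks via mid-contour normal
    trajectories, velocity/signal kymographs and velocity-peak-aligned
    statistics. The same pipeline applies to simulated and experimental
    stacks, enabling direct quantitative comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    deSolve,
    EBImage,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
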