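Package: pullgeom
Title: Force Spectroscopy and Steered-MD Pulling-Geometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for single-molecule force spectroscopy (SMFS)
    retraction curves and steered molecular dynamics (SMD) pulling
    trajectories. Converts raw AFM channels to force-extension traces,
    transforms them into contour-length space through an interpolated
    worm-like-chain model, detects unfolding events and ddFLN4-style
    fingerprints, and extracts terminal rupture events. Fits rupture-force
    distributions with single- and multi-component Bell-Evans mixtures,
    builds dynamic force spectra, computes binding-pocket lid-opening
    metrics from trajectories, and traces force propagation through
    contact-filtered correlation networks with optimal and suboptimal
    path enumeration. Includes synthetic-data generators with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    bio3d,
    stats,
    utils,
    graphics,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
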