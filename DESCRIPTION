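Package: jointcoord
Title: Quantifying Changes in Inter-Joint Coordination (JcvPCA and JsvCRP)
Version: 1.0.0
Authors@R:
    person("Movement Analysis", "Toolkit Developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools to quantify how inter-joint coordination changes between two
    sets of repeated movements. Implements JcvPCA (joint contribution variation
    via principal-component reprojection: PCA on a reference dataset,
    reprojection of a comparison dataset into that frame, re-PCA, and
    subtraction of absolute joint weights) and JsvCRP (joint synchronization
    variation via continuous relative phase: phase-portrait angles, pairwise
    relative-phase curves, and the area between mean curves). Includes readers
    and writers for multi-repetition joint-angle CSV trees, a natural-variability
    thresholding procedure based on repeated random splits of a baseline
    condition, a synthetic movement generator (sinusoidal joint pairs and a
    two-link planar arm executing four named coordination strategies), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    optparse,
    pracma,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
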