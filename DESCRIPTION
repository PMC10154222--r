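Package: topotrace
Title: Single-Molecule Analysis of Topoisomerase II Action on DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-molecule experiments probing type II
    topoisomerase activity on DNA. Implements a coarse-grained worm-like-chain
    Monte Carlo simulator of DNA looping (umbrella sampling with harmonic
    restraints, weighted-histogram unbiasing, Jacobson-Stockmayer J-factors in
    nanomolar units, with or without a fixed internal protein-induced bend),
    polymer elasticity models for dsDNA and ssDNA with force/extension/contour
    inter-conversion, nearest-neighbor equilibrium DNA unzipping baselines, and
    analysis pipelines for optical-trap stretching traces (loop-rupture
    detection, loop sizing, compaction, tether survival kinetics), unzipping
    roadblock metrics (cross-correlation alignment, interaction range, rupture
    force, breakage probability), and magnetic-tweezers supercoil relaxation
    (hat-curve calibration, dwell-time pause detection, pause-free and mean
    relaxation rates, trapped-supercoil sizing). Seeded synthetic-trace
    generators reproduce the statistical structure of each assay so every stage
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    signal,
    minpack.lm,
    survival,
    pracma,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
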