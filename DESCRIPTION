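Package: ionpmf
Title: Umbrella Sampling, WHAM and Minimum Energy Path Analysis for Ion
    Permeation Free-Energy Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs 1D and 2D potentials of mean force from biased
    umbrella-sampling window time series with the self-consistent weighted
    histogram analysis method (WHAM), extracts minimum energy paths and
    free-energy barriers on 2D maps with the string method, and attaches
    block-average error bars by repeating the full analysis on consecutive
    trajectory blocks. Includes a seedable synthetic-data module (analytic
    multi-well free-energy landscapes sampled by overdamped Langevin
    dynamics) emulating the umbrella-sampling protocol used for ion
    permeation through the selectivity filter of voltage-gated sodium
    channels, plus structural snapshot analyses: source-partitioned ion
    coordination shells, off-axis ion displacement by axial band, and
    cavity water counting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
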