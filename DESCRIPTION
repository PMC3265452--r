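Package: dopscreen
Title: Analysis Chain for a Cell-Based Mosquito Dopamine-Receptor Antagonist Screen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of a luminescence-reporter antagonist screening
    campaign against the Aedes aegypti D1-like dopamine receptor AaDOP2: checkerboard
    plate quality control with standard and replicate-adjusted Z-factors, per-plate
    background subtraction and percent-inhibition normalization, antagonist-control
    threshold derivation and hit calling, four-parameter logistic EC50/IC50 estimation
    with activity censoring, cross-receptor fold selectivity and rank-order potency
    correlation, and larval dose-mortality LC50/LC90 analysis. Includes synthetic-data
    generators with known ground truth that emulate the 384-well screen design, so
    every stage is testable for planted-truth recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
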