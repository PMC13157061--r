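Package: wormpharm
Title: Pharmaco-Behavioral Quantification of C. elegans Locomotor Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying drug-induced changes in Caenorhabditis elegans
    swimming locomotion from multi-animal tracker output, built around an
    engineered mu-opioid receptor (tgMOR) assay. Provides a synthetic tracker-table
    generator with Hill/Emax dose-effect and exponential onset/recovery kinetics,
    well-level quality control, baseline/vehicle/body-size normalization layers,
    AUC-based response magnitude (percent of maximum possible speed reduction),
    time-to-maximum-effect and set-time-point statistics, an ANOVA/t-test
    comparison harness with Bonferroni correction, and global protein alignment
    with identity/similarity percentages for orthology comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    emmeans,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
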