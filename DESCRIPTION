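Package: tsage
Title: Tissue-Specific Epigenetic Age Acceleration from Methylation Clocks
Version: 1.0.0
Authors@R: person("tsage", "authors", role = c("aut", "cre"),
    email = "tsage-maintainers@example.org")
Description: Applies linear DNA-methylation clocks to beta-value matrices
    from paired sperm and blood samples, runs sample-level quality filters
    (beta-distribution bimodality, DLK1 somatic-contamination sentinel,
    median-intensity cutoff, chronological-age confound check), computes
    mean-matched germ-line age differential (GLAD) scores, and performs the
    two-group comparison battery (Welch t-tests, paired predicted-age
    differences, predicted-versus-chronological regressions). Ships a
    synthetic methylome generator with known ground truth so the whole
    pipeline is testable by parameter recovery, plus a power-simulation
    utility for two-group designs with unequal sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
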