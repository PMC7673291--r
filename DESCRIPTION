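Package: sporedormancy
Title: Single-Spore Dormancy Kinetics, Germination Landscapes and
    Threshold-Death Simulation for Yeast Spores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for quantifying dormancy-to-death dynamics of
    budding-yeast spore bags from single-cell measurements. Estimates the
    germination probability landscape over glucose concentration and
    gene-expression capacity, fits four-parameter logistic dose-response
    curves, extracts the minimum glucose concentration guaranteeing
    germination by inverse logistic regression, fits exponential production
    kinetics with lag detection to per-spore fluorescence traces, estimates
    population half-lives by first-crossing linear interpolation, decomposes
    production and degradation rates from drug-perturbation comparisons, and
    forward-simulates a threshold-crossing death model with per-spore
    molecular pools. A synthetic-data generator with lognormal capacity
    heterogeneity emulates the statistical structure of the microscopy data
    so that every stage is testable without raw images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
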