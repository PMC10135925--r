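Package: kolmoagg
Title: Hydrodynamic Stress Statistics and Cell-Aggregate Size Distributions
    in Shaken and Stirred Bioreactors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing of exported turbulence fields from bioreactor
    CFD simulations into specific power input, Kolmogorov length-scale
    statistics and hydrodynamic heterogeneity; grid-convergence-index (GCI)
    mesh verification by Richardson extrapolation; closed-form operating-point
    correlations for orbitally shaken flasks (phase number, axial Froude
    number, unbaffled-flask power correlation) and stirred tanks (Reynolds
    and Newton numbers, tip speed, power correlation) plus the
    oxygen-transfer-limited cell-density ceiling; a geometric cluster-size
    distribution model for suspension-cell aggregates with moment and
    maximum-likelihood estimators, chi-squared and G goodness-of-fit tests,
    and a linear link from the mean Kolmogorov length to the geometric
    parameter for in-silico prediction of aggregate size distributions;
    growth-curve reductions and seeded synthetic-data generators for every
    input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
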