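Package: bsperc
Title: Percentile Inference for the Birnbaum-Saunders Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distribution functions, maximum-likelihood fitting, and four
    interval constructions for percentiles of the two-parameter
    Birnbaum-Saunders (fatigue-life) distribution: generalized confidence
    intervals built from generalized pivotal quantities, bias-corrected
    parametric bootstrap percentile intervals, equal-tailed Bayesian credible
    intervals from an exact generalized ratio-of-uniforms posterior sampler
    with inverse-gamma priors, and highest posterior density intervals.
    Includes a Monte Carlo engine for coverage probability and average length
    studies, and AIC-based comparison against six competing positive-data
    families, with bundled daily PM2.5 series from two northern Thai
    provinces.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
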