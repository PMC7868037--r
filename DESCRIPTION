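Package: cortikin
Title: Bayesian Multi-Tissue Cortisol Kinetics from Time-Course Assays
Version: 0.1.0
Authors@R:
    person("IPHC", "Analytics", email = "dev@example.org", role = c("aut", "cre"))
Description: Tools for analysing stress-hormone time courses measured in more
    than one tissue. Fits a Bayesian cubic regression of cortisol
    concentration on time post-stimulus by Gibbs sampling, screens posterior
    draws against a-priori kinetic constraints, and derives peak/minimum
    timing, peak concentration, and distribution and elimination times with
    equal-tailed 90 percent credible intervals. Treatment and control
    posteriors are compared through proportional (ratio) curves with credible
    bands and through exceedance probabilities against baseline thresholds.
    Includes a two-compartment (plasma to epidermal mucus) synthetic-data
    generator that reproduces a tank-based repeated-sampling design with
    known ground truth for recovery testing, plus validated CSV input/output
    and immunoassay coefficient-of-variation QC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
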