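Package: selsurv
Title: Microsimulation of Selective Survival Bias in Dementia Incidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decision-analytical microsimulation of selective survival
    (collider) bias in estimated sex/gender differences in dementia
    incidence. Simulates cohorts of 50-year-olds under a sharp null of no
    sex/gender effect on dementia, with a latent selection characteristic U
    that lowers cognition and, in some causal scenarios, survival.
    Mortality follows a piecewise-exponential model with U-frailty
    calibrated to lifetable band survival; dementia onset arises when a
    quadratic latent growth curve of cognition crosses an age-constant
    cutoff or a random shock occurs, calibrated to men's age-specific
    incidence rates. Women-vs-men incidence rate ratios are aggregated
    across Monte-Carlo iterations as the exponentiated mean log IRR with
    percentile intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
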