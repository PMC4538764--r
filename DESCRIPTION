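Package: swtpower
Title: Sample Size and Power Calculations for Stepped Wedge Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, power and sample-size tools for stepped wedge
    cluster-randomised trials. Implements the closed-form variance and
    power calculations of the Hussey-Hughes model for cross-sectional
    designs, the Woertman correction-factor design effect, the standard
    cluster-randomised-trial inflation factor, and the Moulton log-rank
    design effect for survival-type outcomes. A simulation engine
    generates trial data from generalized linear mixed data-generating
    processes (continuous, binary and count outcomes; cross-sectional or
    closed-cohort sampling; fixed, linear, categorical or random time
    effects; random intervention effects), fits the matching mixed model
    and estimates power by Monte Carlo, including minimum-cluster
    searches, sensitivity grids and a Bayesian variant with priors on
    design parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
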