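Package: fovadapt
Title: Motor Adaptation Analysis for Fish-Operated-Vehicle Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-body motor adaptation experiments in
    which a fish steers a wheeled vehicle (a "fish operated vehicle") from a
    start point to a target under rotational perturbations of the
    heading-to-motion mapping. Provides trajectory-level performance metrics
    (success, signed angular error, efficiency-adjusted path length), a
    hierarchical Bayesian exponential learning-curve model with
    measure-specific likelihoods (Poisson, Student-t, Gamma) sampled with
    JAGS, posterior stage comparisons via highest-density intervals and
    regions of practical equivalence (aftereffect, savings), and a synthetic
    cohort simulator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
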