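Package: seriesmr
Title: Allelic-Series Mendelian Randomization for Drug-Target Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for validating drug targets with
    human genetics, built around the allelic-series design used to evaluate
    Lp-PLA2 (PLA2G7) as a coronary-heart-disease target. Generates synthetic
    multi-ancestry case-control cohorts carrying functional variants under
    Hardy-Weinberg equilibrium, estimates per-allele and per-carrier effects
    on enzyme activity (linear regression) and disease (logistic regression),
    collapses rare loss-of-function alleles into carrier burdens with a
    seqMeta-style combined score test, pools estimates by fixed-effect
    inverse-variance meta-analysis with Cochran's Q and I-squared, rescales
    genetic and pharmacological effects onto a common reference scale via
    Wald ratios, and computes analytic and simulation-based study power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
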