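Package: cartmsm
Title: Marginal Structural Models for Comparative Effectiveness of
    Antiretroviral Regimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative-effectiveness analyses of combination
    antiretroviral therapy (cART) regimens in longitudinal cohorts with
    semiannual visits. Implements regimen classification (cART, PI/NNRTI/INSTI
    class hierarchy with pharmacokinetic boosters), visit-pair construction and
    derivation of switching, adherence and HIV RNA suppression outcomes,
    clinical covariate thresholds, restricted quadratic splines for age,
    stabilized inverse-probability-of-treatment-and-censoring (IPTC) weights
    for a 7-category time-varying treatment with percentile truncation and
    balance diagnostics, modified Poisson regression with cluster-robust
    sandwich variance for rate ratios, multivariate-normal multiple imputation
    with Rubin's-rules pooling, and an end-to-end weighted analysis pipeline.
    A longitudinal cohort simulator with treatment-confounder feedback,
    informative dropout and configurable true regimen effects provides
    ground-truth marginal rate ratios via g-computation for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
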