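Package: fwdecomp
Title: Four-Way Mediation-Interaction Decomposition of Health Disparities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal mediation-interaction analysis for disparities in incident
    dementia, with C-reactive protein as a marker of systemic inflammation.
    Implements the four-way decomposition of a total effect on the excess
    relative risk scale into a controlled direct effect, reference interaction,
    mediated interaction, and pure indirect effect, estimated by direct
    counterfactual imputation from Poisson (log link, person-time offset) and
    mediator regression models, with percentile-bootstrap inference. Includes an
    interventional (randomized-analog) g-formula estimator for settings with
    exposure-affected mediator-outcome confounders, mediational E-values, a
    calibrated synthetic cohort generator with a Monte-Carlo ground-truth
    oracle, and cohort-construction utilities (Langa-Weir cognitive
    classification, interval-censored incident outcomes, mediator
    dichotomization at a fixed or percentile threshold).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
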