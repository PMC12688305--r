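Package: moralcomp
Title: Computational Modelling of Guilt- and Shame-Driven Compensation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how people convert harm and responsibility
    into guilt, shame and compensatory behaviour in a 4x4 harm-by-responsibility
    interpersonal game. Provides the trial schedule and token economy of the
    game, a synthetic-data generator for decisions, emotion ratings,
    manipulation checks and trait scores, an eight-model utility family
    (responsibility diffusion vs. harm amplification) with a softmax choice
    rule, per-participant maximum-likelihood fitting with coarse-grid
    initialisation and BIC model comparison, model validation by simulation
    (predictive accuracy, parameter recovery, parameter independence), and the
    behavioural statistics stages: repeated-measures manipulation checks,
    linear mixed-effects emotion and compensation regressions with Wald
    coefficient comparison, per-participant sensitivity extraction,
    Pearson-Filon tests for dependent correlations, percentile-bootstrap
    mediation, and trait correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
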