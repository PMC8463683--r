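Package: metacheck
Title: Metacognition and Uncertainty-Guided Checking Behavior
Version: 0.1.0
Authors@R: person("Metacheck", "Maintainers", email = "maintainers@metacheck.dev",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how perceptual
    uncertainty drives checking behavior in two-alternative forced-choice
    perceptual tasks. Provides a seeded synthetic-cohort generator (signal
    detection theory observers with confidence, adaptive psychometric
    calibration, paired confidence forced choice, Poisson checking policies),
    estimators of explicit (meta-d'/M-ratio) and implicit (confidence
    modulation index) metacognitive sensitivity, and mixed-effects inference:
    Poisson and logistic generalized linear mixed models with subject and
    observation-level random intercepts, Wald tables, equality-constrained
    likelihood-ratio tests, variance inflation factors, parametric bootstrap
    confidence intervals, and exact Wilcoxon signed-rank tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
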