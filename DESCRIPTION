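Package: csutrial
Title: Simulation and Analysis of Dose-Ranging Trials in Chronic
    Spontaneous Urticaria
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end machinery for randomized dose-ranging trials in
    chronic spontaneous urticaria (CSU): patient-diary endpoint scoring
    (daily UAS, UAS7 and its itch/hive components, responder rules,
    time to minimally important difference), basophil histamine release
    assay (BHRA) normalization and positivity, IgG-anti-FcERI
    competition-ELISA quantification with four-parameter-logistic
    standard curves and upper-normal-range thresholding, longitudinal
    efficacy analysis by mixed models for repeated measures (MMRM) with
    unstructured covariance plus LOCF/BOCF sensitivity ANCOVA, subgroup
    and Spearman correlation analyses, Kaplan-Meier time-to-event
    estimation, and design-stage tools (dropout-adjusted power,
    stratified permuted-block randomization, Bayesian
    posterior-predictive go/no-go). A synthetic-cohort generator with a
    latent-class autoimmunity structure stands in for access-controlled
    patient data so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    emmeans,
    survival,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
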