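Package: surveymime
Title: Correcting Self-Report Bias in Health Interview Surveys by
    Multiple Imputation for Measurement Error
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and correcting measurement error in
    self-reported health-interview-survey data when an examination-survey
    validation subsample with objective measurements is available.
    Implements agreement diagnostics (Bland-Altman limits of agreement,
    intraclass correlation, Cohen's kappa, McNemar's test, diagnostic
    accuracy), regression calibration with Wald-screened interaction
    terms, a chained-equations multiple-imputation engine for measurement
    error (predictive mean matching, Bayesian logistic draws, and
    random-forest donor imputation), survey-weighted prevalence
    estimation with Taylor-linearized design variance, Rubin's-rules
    pooling with Barnard-Rubin degrees of freedom, and a synthetic survey
    generator emulating the joint interview/examination design so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
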