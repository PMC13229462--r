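Package: repconf
Title: Confidence Metrics for Repeated Categorical Outputs of Stochastic
    Answer Generators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for measuring and evaluating the diagnostic confidence of
    stochastic answer generators (such as multimodal large language models)
    that are queried repeatedly on multiple-choice cases.  Implements
    self-reported, consistency-based (Shannon entropy, relative entropy
    score, majority-vote percentage) and hybrid (Top Weighted Score)
    confidence metrics with their representative-answer rules, plus the
    accompanying evaluation stack: DeLong ROC AUC, Spearman association with
    interpretation bands, fixed-bin expected calibration error and binary
    Brier score with bootstrap confidence intervals, Mann-Whitney group
    comparisons, Cochran Q across repetition depths, Fleiss kappa
    repeatability, Fisher-exact temporal holdout, and per-call resource
    accounting.  A Dirichlet-multinomial response simulator generates logs
    with the statistical structure the analysis assumes, so the whole
    pipeline is testable without querying any model API.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
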