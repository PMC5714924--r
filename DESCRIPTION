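Package: casefindr
Title: Claims-Based Case-Finding for Non-Small Cell Lung Cancer with a
    Diagnostic-Accuracy Validation Battery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a treatments-and-tests case-finding algorithm that
    classifies lung-cancer patients in administrative claims data as
    non-small cell (NSCLC) versus small cell (SCLC), together with the
    statistical machinery needed to validate any such claims-based
    phenotyping rule against a gold standard: 2x2 diagnostic-accuracy
    measures with confidence intervals (sensitivity, specificity, predictive
    values, accuracy, diagnostic odds ratio), binary-test AUC, the DeLong
    test for correlated ROC curves, and hierarchical logistic regression for
    covariate robustness. A synthetic administrative-claims generator with
    configurable subtype prevalence, guideline-concordant and crossover
    regimen assignment, demographics, and enrollment spans makes the whole
    pipeline runnable and testable without access to proprietary claims
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
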