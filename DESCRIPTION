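Package: iscr
Title: Immunoscore-Style Tumor-Infiltrating Lymphocyte Scoring and
    Pathological Complete Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies CD3+ and CD8+ tumor-infiltrating lymphocyte
    densities (cells/mm^2) in the center-of-tumor and invasive-margin
    compartments of digitized tumor sections, derives ROC/Youden-index
    optimal cut-offs per marker and compartment, combines the resulting
    high/low calls into the five-tiered Immunoscore for Clinical Research
    (ISCR, 0-4) and its biopsy (CT-only, 0-2) variant, and runs the full
    association analysis against pathological complete response after
    neoadjuvant chemotherapy: Pearson chi-square, Fisher exact
    (hypergeometric enumeration), Mann-Whitney U, odds ratios, positive and
    negative predictive values with exact Clopper-Pearson intervals, and
    univariate logistic regression fitted by iteratively reweighted least
    squares. Includes a synthetic-slide spatial simulator (homogeneous
    Poisson cell point processes over polygonal compartments) and a
    synthetic-cohort generator with right-skewed subtype-dependent density
    distributions, a logistic outcome model, and tumor-size-linked
    invasive-margin missingness, so the whole pipeline is testable without
    patient-level data. Reference contingency tables from a published
    103-patient early breast cancer cohort ship as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
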