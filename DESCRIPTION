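Package: ggnrads
Title: Risk Stratification of Pulmonary Ground-Glass Nodules with
    Complementary Lung-RADS and Deep-Learning Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for rule-based risk stratification of
    pulmonary ground-glass nodules (GGNs). Implements the complementary
    Lung-RADS 1.1 categorization from GGN-vessel-relationship type and
    nodule size, malignancy-score binning, the score-driven category
    upgrade scheme, binarization at the category 4A neoplasm point, and a
    full diagnostic-metric panel (precision, recall, accuracy, F-beta,
    Matthews correlation coefficient, single-operating-point ROC AUC).
    Includes a calibrated synthetic screening-cohort generator with a
    closed-form operating-characteristics oracle, cohort CSV input/output,
    and report rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
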