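Package: mwrisk
Title: Breast Cancer Risk Assessment from Microwave Radiometry and
    miRNA Oncopanels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes bilateral temperature-asymmetry statistics
    (Qmax, k_int, k_skin, R) from paired skin (infrared) and internal
    (microwave) breast thermograms, classifies examinations against
    published decision thresholds, builds a thermogram feature space
    for low/high-risk classification, and scores an eight-marker
    circulating miRNA oncopanel by direction-aware fold change.
    Includes a calibrated synthetic-data generator for thermograms and
    panels, a stand-in risk classifier, a rule-based fusion of the
    radiometric and molecular results into a single patient
    assessment, and CSV/JSON readers and writers with a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    nnet,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
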