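Package: ebcmir
Title: Qualitative Exhaled-Breath MicroRNA Scoring, Airway Topography
    Similarity, and Case-Control Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for qualitative analysis of microRNAs measured in exhaled
    breath condensate (EBC) by intercalating-dye RT-qPCR. Converts well-level
    Ct and melt-temperature readings into binary present/absent microRNA
    calls under melt-curve and cycle-threshold rules, computes housekeeper
    normalised delta-Ct matrices, quantifies within-individual similarity of
    binary microRNA profiles across airway sampling levels with a
    Hamming-distance statistic and its permutation test, and compares
    clinical-only against clinical-plus-microRNA case-control classifiers
    using covariate-adjusted logistic regression and random-forest models
    evaluated by repeated cross-validation and resampled ROC AUC. A
    synthetic-data module generates qPCR plates, multi-tissue profile sets
    and case-control cohorts with planted effects so the full pipeline can
    be exercised and validated without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    pROC,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
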