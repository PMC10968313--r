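Package: MultiViewOmics
Title: Multi-View Ensemble Learning and Stability Selection for Parallel
    Multi-Omics Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Supervised learning pipeline for high-dimension, low-sample-size
    (HDLSS) parallel multi-omics cohorts with binary phenotypes. Implements
    three data-integration strategies (early concatenation, intermediate
    shrinkage-based selection, late multi-view consensus ensembles of
    per-layer logistic learners), smoothed-bootstrap training-set
    augmentation, repeated leave-one-out cross-validation, consistent-feature
    stability selection with a label-permutation null, and fold-change
    validation of selected features. Includes a synthetic quadra-omics cohort
    generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
biocViews: Classification, Proteomics, Metabolomics, Lipidomics,
    Transcriptomics, FeatureExtraction, MultipleComparison
Config/testthat/edition: 3
RoxygenNote: 7.3.3
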