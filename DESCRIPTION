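Package: engramsig
Title: Activity-Induced Transcriptional Signatures and Reactivation
    Prediction in Single Nuclei
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-nucleus RNA-seq studies of
    activity-induced transcription in hippocampal neurons. Implements
    nucleus-level quality control, hierarchical iterative clustering with
    random-forest refinement for cell-type identification, a
    reproducibility-optimized differential expression test with bootstrap
    tuning and permutation p-values, temporal gene-group classification
    (early, sustained and late signatures), principal-component signature
    scoring with Newly Activated versus Reactivated labeling, random-forest
    prediction of engram reactivation with ROC evaluation, hypergeometric
    set-overlap and enrichment tests, and a GO-term weighted cosine gene
    distance. A negative-binomial simulator with full ground truth
    generates data with the statistical structure the analysis assumes, so
    every stage can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Matrix,
    Rtsne,
    randomForest,
    cluster,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
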