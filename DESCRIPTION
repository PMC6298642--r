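Package: EPLeakage
Title: Feature-Sharing Leakage Diagnostics for Enhancer-Promoter
    Interaction Benchmarks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to audit and demonstrate test-set contamination in
    supervised enhancer-promoter (EP) interaction prediction. Candidate EP
    pairs share epigenomic features whenever they share a promoter or have
    overlapping intervening windows; random cross-validation then rewards
    memorization of shared features rather than generalization. The package
    provides an S4 container for EP-pair datasets with enhancer/promoter/
    window (E/P/W) feature blocks, a synthetic-data generator that
    reproduces the sharing and class-imbalance structure of real EP
    training sets with a tunable (default zero) genuine label signal,
    structural leakage audits (promoter-sharing matrices, contamination
    accuracy, window-overlap components), leakage-free cross-validation
    partitioners with contamination certificates, and a train/test
    benchmark harness over gradient boosting, random forests and SVMs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    withr,
    xgboost,
    ranger,
    e1071,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Epigenetics, GeneRegulation, MachineLearning, Software
RoxygenNote: 7.3.3
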