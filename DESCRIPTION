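Package: qimbalance
Title: Quality-Imbalance Analysis for Case-Control Sequencing Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how strongly per-sample quality is confounded with
    the case/control design of a sequencing study and measures the downstream
    consequences. Computes the quality-imbalance (QI) index of a dataset as
    the absolute point-biserial correlation between per-sample low-quality
    probabilities and the group label (with Spearman and central-tendency
    difference alternatives), derives recurrent low- and high-quality marker
    genes across datasets, bins ChIP-seq peaks to fixed-width genomic windows
    for the same analysis, measures the inflation of differential-expression
    results under quality imbalance via quality-stratified subsets, and
    evaluates two mitigation strategies (quality covariate, IQR outlier
    removal). Includes a negative-binomial simulator with planted quality and
    disease effects and a tunable quality-imbalance level, so every analysis
    is exercisable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    DESeq2
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    rtracklayer,
    jsonlite,
    optparse
biocViews: QualityControl, RNASeq, ChIPSeq, DifferentialExpression,
    BatchEffect, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
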