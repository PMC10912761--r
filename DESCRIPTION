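Package: reopair
Title: Relative Expression Ordering Gene-Pair Signatures for Transcriptome
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Mines within-sample relative expression orderings (REOs) from
    gene-by-sample expression matrices to build qualitative gene-pair
    signatures for two-class diagnosis. Provides stable gene-pair mining,
    reversal-pair detection between classes, gene whitelist filtering,
    ternary {0, 1, -1} encoding of samples into pair space, mRMR
    (mutual-information) and MRMD (Pearson relevance plus cosine-distance
    redundancy) feature ranking, incremental feature selection over a panel
    of classifiers (RBF SVM, k-nearest neighbours, decision tree, logistic
    regression, XGBoost, AdaBoost with decision stumps, naive Bayes), ROC
    and confusion-matrix metrics with DeLong confidence intervals, a
    packaged 11-pair hepatocellular-carcinoma signature, and a synthetic
    cohort generator with planted reversal pairs for end-to-end testing.
    Because only within-sample orderings are used, all results are invariant
    to monotone per-sample transforms and hence normalization-free and
    cross-platform.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    rpart,
    class,
    xgboost,
    pROC,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'classifiers.R'
    'featureRank.R'
    'metrics.R'
    'ifs.R'
    'io.R'
    'reo.R'
    'pipeline.R'
    'reopair-package.R'
    'signature.R'
    'synthdata.R'
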