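Package: methylWave
Title: Sequence-Based Prediction of DNA Methylation Sites from
    Physicochemical and Compositional Window Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the methylation state of cytosines from fixed-length
    DNA windows centred on the candidate site. Each window is encoded into a
    612-dimensional feature vector built from four extractors: overlapping
    1/2/3-gram occurrence counts (84), multivariate mutual information over
    unordered nucleotide tuples (30), discrete-wavelet-transform band
    statistics over six dinucleotide physicochemical property tracks (312),
    and lagged autocovariance of the same tracks (186). Training data can be
    de-duplicated, purged of cross-class conflicts and balanced with SMOTE;
    classification uses a sparse Bayesian (relevance vector) Gaussian-kernel
    model or a support vector machine. Evaluation follows target-jackknife
    cross-validation (synthetic samples train but are never tested) or a
    chromosome-parity holdout, reporting ACC, MCC, sensitivity, specificity,
    ROC and AUC, with SVM-weight importance ranking and incremental feature
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
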