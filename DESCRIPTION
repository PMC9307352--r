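Package: ovaclass
Title: Feature Extraction and Classification of Ovarian Cancer Microarray
    Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable implementation of a microarray gene-expression
    classification pipeline for ovarian cancer: per-gene ANOVA/volcano gene
    filtering, five clustering- and transform-based feature extraction
    methods (fuzzy C-means, softmax discriminant scoring, Hilbert envelope,
    FFT magnitude, DCT-II), correlation-distance feature selection, six
    regression-style classifiers trained against 0.9/0.1 class targets,
    stratified 10-fold cross-validation, and a nine-metric confusion-matrix
    report (accuracy, precision, F1, MCC, Fowlkes-Mallows, error rate,
    Jaccard, classification success index, MSE). Includes a seeded synthetic
    microarray generator so the whole pipeline is testable offline, and an
    audit utility that checks published metric tables against their
    confusion matrices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    e1071,
    pracma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    class
Config/testthat/edition: 3
RoxygenNote: 7.3.3
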