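Package: cnvclass
Title: Multi-Class Clinical Significance Classification of Copy Number Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workbench for training, calibrating, explaining and benchmarking
    multi-class (benign / uncertain / pathogenic) classifiers of copy number
    variant (CNV) clinical significance. Implements a 17-feature annotation
    engine (genomic position, CNV composition, functional annotation,
    population frequency, smoothed conservation, dosage sensitivity),
    ClinVar-style dataset-curation rules, per-CNV-type model selection with
    cross-validated architecture ranking and randomized hyperparameter search,
    isotonic probability calibration, exact tree Shapley-value attributions
    with beeswarm and force-plot exports, a one-vs-rest benchmarking harness,
    and a self-contained synthetic annotation-bundle generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    ranger,
    rpart,
    nnet,
    glmnet,
    e1071,
    MASS,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
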