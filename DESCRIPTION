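Package: pseudofuse
Title: Confidence-Guided Pseudo-Labelling with Dual-Branch Feature Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semi-supervised self-training pipeline for multi-class
    grayscale image classification in low-annotation regimes. Unlabelled
    images are pseudo-labelled by thresholding a classifier's softmax
    confidence, optionally requiring the consensus of two independently
    trained network branches, and the accepted samples are merged into the
    training set over an iterative rejection loop with a relaxing threshold
    schedule. A dual-branch architecture (a compact texture-oriented
    convolutional network on grayscale input and a pluggable
    feature-extractor branch on RGB input) can be fused by concatenating
    intermediate feature vectors under a shared dense head. The package
    ships a seeded four-class phantom-image generator that emulates a brain
    MRI tumor-classification task at desk scale, stratified split utilities,
    image-folder input/output, evaluation metrics, and a statistical
    comparison suite (paired t-test, binomial proportion intervals, Cohen's
    d, McNemar's test with continuity correction, Cohen's kappa, percentile
    bootstrap). A compact neural-network engine (im2col convolution,
    max-pooling, dense layers, dropout, Adam/Adamax) is implemented in base
    R so that the whole pipeline runs deterministically on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'backbones.R'
    'cli_config.R'
    'data_model.R'
    'geometry.R'
    'metrics.R'
    'nn.R'
    'phantoms.R'
    'preprocessing.R'
    'pseudo_labeling.R'
    'pseudofuse-package.R'
    'ssl_pipeline.R'
    'stats_suite.R'
    'utils.R'
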