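Package: SeizureAE
Title: Shallow Autoencoder Feature Learning for Single-Channel EEG
    Seizure Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A hybrid epileptic seizure detector for single-channel EEG:
    1-second epochs are compressed by a single-hidden-layer autoencoder
    (saturating-linear encoder, linear decoder) trained with the scaled
    conjugate gradient method to minimize reconstruction error, and the
    encoded representation is classified as ictal or interictal by
    conventional classifiers (weighted k-nearest neighbors, Gaussian-kernel
    support vector machine, quadratic discriminant analysis, kernel naive
    Bayes, decision tree, softmax). Includes a seeded synthetic spike-wave
    EEG generator, EDF and Bonn-style ASCII readers, epoch segmentation and
    splitting utilities, channel-wise evaluation sweeps, and an
    arithmetic-operation complexity model of the deployed encoder plus
    classifier pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    kernlab,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'synthetic.R'
    'io-edf.R'
    'io.R'
    'scg.R'
    'autoencoder.R'
    'classifiers.R'
    'evaluation.R'
    'complexity.R'
    'pipeline.R'
    'cli.R'
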