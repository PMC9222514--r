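Package: osteoDSSAE
Title: Osteosarcoma Histology Patch Classification with a Wind-Driven-Optimized
    Deep Stacked Sparse Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies histopathology image patches into viable tumor,
    non-viable (necrotic) tumor, and non-tumor classes. Provides
    edge-preserving bilateral and Gaussian pre-filtering with contrast
    enhancement, a lightweight SqueezeNet-style convolutional feature
    extractor built from fire modules, a deep stacked sparse autoencoder
    (DSSAE) classifier with Kullback-Leibler sparsity and L2 weight penalties
    trained by scaled conjugate gradient, and Wind Driven Optimization (WDO)
    of the classifier hyperparameters against a classification-error fitness.
    Includes a per-class metric suite (accuracy, precision, recall, F-score,
    MCC, geometric mean), a seeded synthetic three-class data generator for
    fully offline testing, and an end-to-end pipeline with reproducible runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
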