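Package: mshisto
Title: Multispectral Texture Classification for Colorectal Histopathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification of multispectral histopathology image cubes
    combining visual- and infrared-spectrum bands. Implements six per-band
    texture descriptors (grey-level co-occurrence statistics, intensity
    moments, Tamura perception features, rotation-invariant local binary
    patterns, rotation-invariant local phase quantization and binarized
    statistical image features), similarity-based band selection by linear
    prediction with optional whitening, global and pairwise feature
    reduction (principal components and feature selection via concave
    minimization), a stacked support-vector-machine ensemble with a linear
    meta-classifier, sub-image label aggregation, and patient-level versus
    image-level cross-validation protocols, together with a seeded
    synthetic multispectral dataset generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    nnet,
    png,
    stats,
    tiff,
    utils,
    graphics
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
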