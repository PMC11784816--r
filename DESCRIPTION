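Package: qgafs
Title: Quantum-Inspired Genetic Algorithm Feature Selection for Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A quantum-inspired genetic algorithm (QGA) for binary
    optimization, and on top of it a wrapper feature-selection pipeline
    (QGA-FS) for class-labeled image data: deep-style feature extraction,
    subset search driven by cross-validated classifier accuracy, retraining
    of a softmax classifier head on the selected features, and a full
    multiclass evaluation suite (precision, recall, F1, Cohen's kappa,
    Matthews correlation coefficient). Includes synthetic generators for
    class-conditional Gaussian feature matrices with known informative
    features and for geometric-motif image directories, so the whole
    pipeline is testable offline, plus a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    MASS,
    nnet,
    png,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
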