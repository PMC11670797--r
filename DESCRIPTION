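Package: erpssid
Title: State-Space Identification Features for Event-Related Potential
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Dimensionality reduction of event-related brain potential (ERP)
    signals by continuous-time state-space system identification. Each
    electrode's averaged ERP waveform is treated as an impulse response and
    realized as a low-order linear system via Hankel-matrix singular value
    decomposition (Kung's algorithm); the 2*nx transfer-function coefficients
    replace the raw samples as classifier features. Includes an order-selection
    search driven by mean squared fitting error, a PCA plus six-classifier
    (KNN, Naive Bayes, decision tree, LDA, SVM, random forest) cross-validated
    evaluation harness with confusion-matrix metrics, a seeded synthetic
    two-class ERP generator with known ground-truth dynamics, and plain-text
    readers/writers plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS,
    class,
    e1071,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
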