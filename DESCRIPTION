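Package: xfall
Title: Cross-Dataset Fall Detection from Tri-Axial Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and cross-dataset evaluation pipeline for
    accelerometer-based fall detection. Generates lab-style and real-world-style
    tri-axial accelerometer recordings, reads and writes SisFall-dialect files,
    aligns fall impacts with a sample-entropy criterion, extracts a 36-dimensional
    time/frequency feature representation per 2.5 s window, trains linear SVM,
    k-nearest-neighbour and random-forest classifiers with sequential backward
    feature selection and grid-search tuning, and quantifies how classifiers
    trained on one domain generalize to the other with accuracy, sensitivity and
    specificity plus nonparametric comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    class,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
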