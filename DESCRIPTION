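Package: twinwave
Title: Dual-Tree Complex Wavelet Features and Twin Support Vector
    Machines for Two-Class Brain MRI Slice Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies two-class cohorts of 2-D brain MRI slices
    (e.g. Alzheimer's disease patients versus healthy controls) from
    dual-tree complex wavelet transform (DTCWT) magnitudes.  Provides a
    from-scratch 2-D DTCWT with Q-shift filter banks (perfect
    reconstruction, near shift invariance, six directional subbands), a
    critically sampled DWT baseline, PCA followed by Fisher linear
    discriminant projection, a linear Twin Support Vector Machine
    solved via its Lagrange duals, repeated stratified k-fold
    cross-validation with the usual confusion-matrix statistics, and a
    synthetic brain-phantom cohort generator so the whole pipeline is
    testable without clinical data.  A small command-line tool exposes
    cohort synthesis, feature extraction and evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    EBImage,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
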