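Package: mammowave
Title: Wavelet-Activated Convolutional Networks for Mammogram Abnormality
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiclass abnormality classification in digital
    mammograms built around a wavelet-activated convolutional network (wCNN).
    Provides contrast-limited adaptive histogram equalization (CLAHE) and
    content-aware seam-carving preprocessing, orthonormal 2D Haar wavelet
    decomposition with low-pass (LL) feature extraction, a Morlet-type
    cosine-Gaussian activation function with its analytic derivative for
    backpropagation, compact CPU builders and training loops for matched
    CNN/wCNN architectures, a DCGAN-style generator/discriminator pair for
    synthesizing under-represented abnormality classes, a full
    confusion-matrix metric suite (accuracy, specificity, sensitivity,
    precision, F1, recall with micro/macro averaging), a seeded synthetic
    mammogram generator for end-to-end testing, and a reproducible pipeline
    orchestrator with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
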