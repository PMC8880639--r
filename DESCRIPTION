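Package: lastkit
Title: Automated Processing of Luria's Alternating Series Test Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A fully automatic pipeline for the paper-and-pencil Luria's
    Alternating Series Test (LAST): scanned grayscale forms are binarized,
    thinned and reduced to a one-dimensional signal form; the slow baseline is
    estimated and removed with the BEADS sparse-signal decomposition; the
    series is split into characters; each character is recognized as an open
    rectangle or triangle using enclosing-shape geometry, Hough line analysis,
    amplitude histograms and band-constrained dynamic time warping; per
    character and per-series features are extracted and normalized against
    the examiner's template characters; the correctness of the alternating
    sequence is scored with a normalized Needleman-Wunsch coefficient; and
    group differences (Parkinson's disease, progressive supranuclear palsy,
    controls) are assessed with Kruskal-Wallis/Dunn statistics and a
    one-vs-one error-correcting-output-codes Gaussian-kernel SVM classifier.
    A synthetic scan generator with exact ground truth (micrographia, drift,
    perseveration, jitter) makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
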