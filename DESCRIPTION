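Package: mss
Title: Marker State Space Panels for Case-Control Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds multi-marker diagnostic panels with the Marker State
    Space (MSS) approach: continuous marker measurements are binarized
    against per-marker thresholds, every sample occupies one of the 2^n
    binary "marker states" of an n-marker panel, and each state is
    assigned to case or control by majority vote of the training samples
    occupying it. The package provides preprocessing for antibody-array
    intensities (replicate geometric means, background subtraction,
    log10 transform, low-signal filtering), an exhaustive search over
    marker combinations and threshold grids, 10-fold cross-validation
    with robustness-based panel selection, exact Boolean minimization of
    state rules into condensed wildcard patterns, a synthetic-data
    generator with planted patient subclasses, and deterministic
    tab-delimited reports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
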