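Package: hemofuse
Title: Fusion-Based Classification of Intracranial Haemorrhage Subtypes on CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end desk-scale pipeline for classifying intracranial
    haemorrhage (ICH) subtypes on grayscale CT slices. Stages: median-filter
    denoising (including a histogram-bisection variant), multilevel Otsu
    thresholding driven by the seagull optimization algorithm (SOA), fused
    capsule-network and inverted-bottleneck feature extraction with
    entropy-based selection, deer hunting optimization (DHO) for
    hyperparameter tuning, and a fuzzy support vector machine (FSVM)
    classifier in which per-sample memberships cap the dual coefficients.
    Ships a synthetic CT-slice generator with class-dependent lesion
    geometry so every stage is testable without external data, plus
    confusion-matrix and per-class metric reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    e1071,
    kernlab,
    MASS,
    RNifti,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
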