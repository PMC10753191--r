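Package: musclephys
Title: Muscle Torque Kinetics, Eccentric Contraction Decrement and Fibre-Type Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal in vivo canine muscle physiology:
    isometric twitch and tetanus torque-trace kinetics (peak and end-of-stimulation
    torque, decile contraction and relaxation time courses, 95% proxies, quality
    control), the eccentric-contraction decrement statistic with its supporting
    regressions, a semi-automated immunofluorescence fibre-typing pipeline
    (bleed-through subtraction, watershed instance segmentation, particle
    filtering, ROI fluorescence measurement and seven-way myosin-based
    classification), Cq-based myosin heavy chain isoform abundance estimation, and
    group statistics with repeated-measures sample-size calculations.
    Parametric generators for torque traces and ground-truth-labelled synthetic
    muscle sections support validation when instrument or microscope data are
    unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    tiff,
    EBImage,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
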