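Package: hiptension
Title: Intraoperative Hip Soft-Tissue Tension from an Instrumented Femoral Head
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intraoperative soft-tissue tension around the
    hip during total hip arthroplasty. Reconstructs three-dimensional joint
    forces from a four-sensor instrumented modular femoral head, transforms
    them from the implant frame to the pelvic frame through the stem-geometry
    rotation chain, segments passive flexion cycles and extracts per-cycle and
    cohort summary statistics (extrema, flexion angle at minimum force, and
    intra-/intersubject coefficients of variation), and independently predicts
    passive hip joint reaction forces with a scaled rigid-segment model of
    Hill-type passive muscle forces under gravity. A seedable synthetic-cohort
    generator emulates 100 Hz sensor recordings over passive flexion cycles so
    every pipeline stage is testable without clinical data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
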