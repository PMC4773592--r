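Package: ocusimon
Title: Simulation and Distributional Analysis of an Oculomotor Simon Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for oculomotor Simon-task experiments in which
    the response is a left/right saccade: generation of balanced session
    designs, simulation of trial outcomes from a dual-route conflict
    accumulator (constant controlled drift plus a pulse of automatic,
    location-driven activation with starting-point variability), rendering of
    300-Hz horizontal gaze traces, saccade detection by Savitzky-Golay
    velocity estimation with an iterative data-driven peak-velocity
    threshold, response extraction and exclusion filtering, conditional
    accuracy functions and delta plots over reaction-time septiles, and
    mixed-effects inference (linear models for latency and delta values,
    logistic models for accuracy) with single-step adjusted post hoc
    contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    ggplot2,
    jsonlite,
    yaml,
    signal,
    lme4,
    multcomp,
    car,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
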