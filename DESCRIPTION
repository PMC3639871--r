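Package: clgf
Title: Coupled Local and Global Feedback Circuits in Multichannel Neural Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how coupled local-and-global feedback (CLGF)
    circuits shape beta and gamma band oscillations and synchrony in
    multichannel neural recordings. Provides delayed Wilson-Cowan oscillator
    simulation (method of steps with fourth-order Runge-Kutta), complex Morlet
    wavelet time-frequency analysis and band power, beta-gamma power switching
    detection, sliding-window phase-locking value (PLV) synchrony, two-sided
    impulse-response feedback network inference with surrogate calibration,
    local/global feedback classification and CLGF motif counting, a
    ground-truth synthetic cohort generator, and the group statistics used to
    compare patient-like and control-like cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
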