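Package: turbodyn
Title: Turbulent Dynamics and Hopf Whole-Brain Modelling of Parcellated BOLD Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale turbulence analysis of parcellated resting-state BOLD
    time series based on the Kuramoto local order parameter (amplitude
    turbulence, information cascade flow and cascade, information transfer,
    node-level metastability, network-level turbulence), together with a
    coupled Stuart-Landau (Hopf) whole-brain model on an exponential
    distance-rule connectome, distance-resolved functional-connectivity
    fitting of the global coupling, in silico perturbation measures
    (susceptibility and information-encoding capability), simulated lesion
    attacks on structural connectivity, and a synthetic cohort generator so
    the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
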