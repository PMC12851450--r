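Package: gliomalatt
Title: Anatomy-Biased Lattice Simulation of Glioblastoma Growth with
    Approximate Bayesian Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A stochastic lattice (cellular-automaton) model of glioblastoma
    xenograft growth in which tumor cells migrate preferentially toward white
    matter and blood vasculature, together with the machinery needed to fit it
    to segmented tumor images: synthetic 3D brain anatomy generation, geometric
    (location-free) summary statistics of binary tumor slices, rejection
    approximate Bayesian computation with local-linear regression adjustment,
    an in-silico benchmark of estimator quality, and treatment-combination
    sweeps over anti-migration/anti-proliferation drug mixes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    RNifti,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
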