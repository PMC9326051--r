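Package: dynspect
Title: Continuous-Acquisition Dynamic Cardiac SPECT Simulation and Gated
    Spatiotemporal Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained forward/inverse laboratory for dynamic
    myocardial perfusion SPECT with a slowly rotating dual-head gamma
    camera. Provides a deformable beating/breathing digital torso phantom
    with tracer kinetics, continuous-rotation acquisition simulation with
    attenuation, depth-dependent collimator response, Poisson noise and
    dual-energy-window scatter correction, cardiac-respiratory gating,
    gated 4D spatiotemporal MLEM reconstruction with cubic B-spline
    temporal bases and per-gate system matrices, one-tissue compartment
    kinetic parameter estimation, and image-quality evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    splines,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
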