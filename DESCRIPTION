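Package: rigidfoot
Title: Planar Gait Simulation and Optimal Control with Rigid Foot-Ground Contact
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying sagittal-plane human walking with rigid
    foot-ground contact. Implements a seven-segment, nine degree-of-freedom
    floating-base rigid-body model driven by agonist-antagonist muscle torque
    generators, two rolling foot-ground contact models (a single ellipse and a
    heel/forefoot double-circle pair), a centre-of-pressure rollback procedure
    that fits foot geometry to stance-phase recordings, multi-phase optimal
    control problems for tracking and predicting walking (direct multiple
    shooting with plastic impact transitions), and a synthetic-data generator
    that emulates stance and gait trials for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
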