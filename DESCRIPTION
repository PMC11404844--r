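Package: exoassist
Title: Simulation of Ideal Motor- and Spring-Based Assistance During Walking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Musculoskeletal simulation pipeline that solves muscle redundancy
    during walking with prescribed kinematics and dynamics by direct-collocation
    trajectory optimization with implicit Hill-type muscle activation and
    contraction dynamics, identifies ideal assistive joint moments for
    motor-based (free unidirectional torque) and spring-based (engageable
    torsional spring) devices, computes per-muscle metabolic rates with a
    Bhargava-family energy model, and summarizes changes in activations, net
    muscle moments and metabolic rates between unassisted and assisted
    conditions. Includes a synthetic gait-trial generator with known ground
    truth, muscle-tendon parameter tuning against fiber-length and passive
    moment-angle targets, and readers/writers for motion-storage and parameter
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    deSolve,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
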