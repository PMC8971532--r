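Package: myostiff
Title: Passive Myocardial Stiffness Estimation from the End-Diastolic
    Pressure-Volume Relationship
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inverse estimation of the passive fiber stiffness constants of a
    reduced Holzapfel-Ogden myocardial constitutive model from geometric,
    fiber-architecture and end-diastolic pressure-volume (EDPVR) features.
    Provides an idealized biventricular geometry generator, a semi-analytic
    inflation solver for a fiber-reinforced incompressible thick-walled
    cylinder, Latin hypercube sampling of the design space, a multilayer
    feed-forward neural-network surrogate trained on simulated EDPVRs,
    permutation feature importance, Klotz-style single-point EDPVR
    reconstruction, and parameter-identifiability diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    lhs,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
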