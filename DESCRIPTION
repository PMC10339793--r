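Package: FlexColloid
Title: Free-Energy Landscapes and Surface Dynamics of DNA-Linked Flexible
    Colloidal Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Microscopic model of multivalent, surface-mobile DNA-linker
    adhesion between a spherical colloid and a rounded cube (superball).
    Computes sequence-level DNA hybridization thermodynamics
    (nearest-neighbor model with monovalent salt correction), Monte Carlo
    estimates of the configurational spaces of mobile linkers, the
    multivalent bond free energy over a discretized superball surface,
    and Metropolis Monte Carlo dynamics of bound spheres hopping on that
    surface. Reproduces the constrained/unconstrained motion transition of
    flexible colloidal molecules with sphere-to-cube size ratio and
    temperature, together with trajectory observables (position
    autocorrelation, in-plane mean displacement, facet occupancy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
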