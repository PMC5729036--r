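Package: kinst
Title: Instanton and Quantum Rate Theories for Kinetic Isotope Effects
Version: 0.1.0
Authors@R:
    person("kinst", "developers", email = "kinst@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for the hierarchy of quantum reaction-rate
    theories used to compute kinetic isotope effects (KIEs): Eyring transition-state
    theory with the Wigner tunneling correction, ring-polymer semiclassical
    instanton rates and ground-state tunneling splittings, and the quantum-instanton
    rate evaluated by path-integral Monte Carlo with thermodynamic and virial
    estimators, Lie-Trotter and Suzuki-Chin factorizations, and thermodynamic
    integration over particle mass.  Model potential-energy surfaces (Eckart
    barrier, quartic double wells, separable barrier-plus-harmonic systems, a
    two-dimensional Morse-based proton-transfer form) are built in, together with
    exact one-dimensional quantum oracles (numerical scattering transmission and a
    sinc-DVR eigensolver) used to validate every approximate method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
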