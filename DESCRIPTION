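Package: msbsim
Title: Brownian Magnetic Nanoparticle Dynamics and Magnetic Spectroscopy Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic rotational-dynamics simulator for Brownian magnetic
    nanoparticles in oscillating applied fields, and the analysis stack used in
    magnetic spectroscopy of nanoparticle Brownian motion (MSB) biosensing.
    Integrates the dimensionless Langevin equation for ensembles of dipole
    orientations with a two-step Heun (Stratonovich) scheme, computes derivative
    harmonic spectra of the magnetization, exposes the master-variable scaling
    law A = xi0/Omega with collapse diagnostics, provides closed-form Debye
    linear-response limits, and fits harmonic-versus-master-variable curves with
    a one-parameter domain-scaled Langevin function.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
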