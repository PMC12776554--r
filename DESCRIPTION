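Package: porekinetics
Title: Ion-Channel Pore Profiling, Permeation Counting, and Kinetic
    Conduction Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for single-channel ion permeation studies of
    the TMEM16A calcium-activated chloride channel and similar pores.
    Provides a Brownian-dynamics generator of ion/water trajectories in a
    model cylindrical pore with a prescribed free-energy landscape and
    applied transmembrane voltage; pore-pathway construction from water
    density with ion-density, Boltzmann-inversion free-energy, and radius
    profiles along the path; permeation-event detection with block currents,
    Poisson confidence intervals and conductance estimation; a three-site,
    seven-state master-equation model of chloride conduction with
    detailed-balance rates coupled to voltage-dependent sequential calcium
    binding, reproducing Ohmic versus outwardly rectifying current-voltage
    behaviour; a one-dimensional nonlinear Poisson-Boltzmann solver for the
    transmembrane potential and electrical distances; and
    conductance-voltage (Boltzmann activation) analysis of whole-cell
    currents.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
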