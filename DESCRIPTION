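Package: tripodCpH
Title: Constant-pH Monte Carlo Titration and Conformational Analysis of a
    Tripodal Aminopyrrolic Sugar Receptor
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-site constant-pH Monte Carlo titration of a tripodal
    diaminopyrrolic mannoside receptor with six titratable secondary amines,
    driven by a screened-Coulomb surrogate for Poisson-Boltzmann site-site
    energies. Provides exact enumeration of the 64 protonation microstates,
    Metropolis sampling with coupled-pair moves, titration curves and
    apparent-pKa fits, symmetry-class analysis of microstate populations, a
    stop-and-go protonation/conformation coupling loop, structural
    descriptors (radius of gyration, symmetry-corrected RMSD, arm-position
    maps), kernel-density free-energy landscapes with
    autocorrelation-corrected errors, and receptor-mannoside interaction
    observables (geometric hydrogen bonds, tail-ring distances, piecewise
    distance-restraint energies). Includes a synthetic conformational
    ensemble generator spanning closed to open arm arrangements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
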