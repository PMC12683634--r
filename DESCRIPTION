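Package: protolysis
Title: Empirical Valence Bond Energetics of Water Protolysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational toolkit for water protolysis
    (2 H2O -> H3O+ + OH-) as the rate-limiting step of l-DOPA autoxidation.
    Converts experimental kinetic and equilibrium data into an anchored
    reaction profile via Eyring-Polanyi and mole-fraction equilibrium
    thermodynamics; provides a two-state empirical valence bond (EVB)
    potential with Morse bonds, Buckingham reactive repulsion and
    geometric-combining Lennard-Jones terms; samples a small water droplet
    containing a reactive hydrogen-bonded dimer with a Langevin (BAOAB)
    integrator under the lambda mapping potential; estimates free energies
    by exponential averaging (Zwanzig), Bennett acceptance ratio (BAR) and
    the EVB free-energy-perturbation/umbrella-sampling combination on the
    energy-gap coordinate; calibrates the off-diagonal coupling and
    gas-phase shift against reference barriers; and evaluates charged
    solvation finite-size corrections (Born, Ewald self-energy) together
    with the counterion thermodynamic-cycle algebra for hydroxide transfer
    between bulk water and a protein site.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
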