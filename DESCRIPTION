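Package: polystab
Title: Finite-Temperature Crystal Polymorph Stability Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale workflow for ranking rigid-molecule crystal polymorphs at
    finite temperature. Combines static lattice energies (Buckingham exp-6
    repulsion-dispersion plus point-charge Ewald electrostatics with analytic
    gradients and Hessians), harmonic lattice-dynamics phonon free energies for
    prescreening and dynamical-stability filtering, and pseudosupercritical-path
    (PSCP) alchemical free energies estimated with an in-house multistate Bennett
    acceptance ratio (MBAR) solver. Includes rigid-body Monte Carlo sampling of toy
    crystals and liquids, solid-solid and melting transition-temperature extraction
    with propagated uncertainties, free-energy decomposition into van der Waals,
    electrostatic and volumetric contributions, synthetic polymorph fixture
    generation, and an end-to-end screening pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
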