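Package: rsbeam
Title: Range-Shifter Beam Modeling for Proton Pencil-Beam Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fermi-Eyges phase-space transport and multiple-Coulomb-scattering
    modeling of range shifters in proton pencil-beam scanning. Implements the
    Highland and Lynch-Dahl scattering formulas, analytical Fermi-Eyges moment
    integrals for a Lexan range-shifter slab, a treatment-planning-style
    V-parameter model built on the five-thirds stopping-power approximation
    (commissioning fits with covariance-determinant constraints, V extraction
    and prediction, emulation of two known planning-system defects), a
    condensed-history Monte Carlo pencil-beam benchmark, a synthetic
    scintillation-screen spot-size data generator, and a comparison pipeline
    that confronts the three methods across range-shifter positions and
    energies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
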