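Package: ngbkin
Title: Hexacoordinate Globin Ligand-Binding Kinetics from Time-Resolved NMR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of slow ligand binding to
    hexacoordinate hemoproteins followed by real-time 1D NMR, with human
    neuroglobin and cyanide as the reference system.  Provides a
    mass-action model of the hexa/penta-coordinate competitive ligation
    scheme for mixtures of heme-orientation isomers sharing one ligand
    pool, closed-form pseudo-first-order limits, a coupled
    binding-equilibrium solver with ligand depletion, a synthetic
    1D-spectrum generator (Lorentzian lineshapes tracking simulated
    species concentrations), Lorentzian peak quantification,
    monoexponential time-course fitting with bootstrap uncertainties, and
    the derivation chain from fitted time constants to second-order
    on-rates, dissociation constants and off-rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
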