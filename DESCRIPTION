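Package: vibrex
Title: Vibronic Excitons and Resonance Energy Transfer in Molecular Dimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Essential-state modelling of interacting donor-acceptor dyes: each
    molecule is described by two diabatic electronic states (neutral and
    zwitterionic) coupled to one effective quantum vibration, and a pair of
    molecules interacts through the electrostatic energy of the doubly
    zwitterionic configuration. The package builds and diagonalizes the
    nonadiabatic vibronic dimer Hamiltonian on a truncated two-mode Fock basis,
    propagates the reduced density matrix with a secular Redfield master
    equation at finite temperature, and computes steady-state absorption,
    time-resolved fluorescence, dynamical and Forster resonance-energy-transfer
    rates, adiabatic potential energy surfaces, and resonance/asymmetry scans
    spanning the crossover between exciton delocalization and incoherent energy
    transfer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    tools,
    utils,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
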