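Package: coevorange
Title: Host-Parasite Range Coevolution Models and Time-Shift Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An ecologically explicit susceptible-infected model of
    host resistance range and parasite infectivity range coevolution:
    endemic equilibria, invasion fitness, selection gradients, singular
    points with convergence-stability classification, Hopf detection by
    grid continuation, and a stochastic trait-substitution simulator.
    Companion statistical tools analyse cross-infection time-shift
    experiments for the three dynamic signatures of antagonistic
    coevolution (arms-race slopes, range fluctuating-selection mean
    squares, clone-level specialism inconsistency), with hierarchical
    phenotype clustering and a synthetic cross-infection tensor
    generator emulating a serial-transfer bacteria-phage study design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    data.table,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
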