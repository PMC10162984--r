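Package: enzopt
Title: Optimal Enzyme Utilization for Elementary Reaction Mechanisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds the elementary rate constants, enzyme-state distribution and
    thermodynamic-displacement allocation that maximize the net steady-state
    flux per total enzyme for an arbitrary elementary enzyme mechanism at fixed
    reactant concentrations and thermodynamics.  The optimization is formulated
    as a mixed-integer linear program: bilinear rate terms are removed by a
    change of variables, elementary thermodynamic displacements are discretized
    with a binary expansion, and the remaining binary-continuous products are
    linearized with the Petersen scheme.  Includes an independent mass-action
    steady-state solver used as a brute-force oracle, variability analysis and
    hit-and-run sampling of alternative and suboptimal operating modes,
    macroscopic Michaelis constant and turnover number estimation from
    in-silico initial-rate experiments, grid scans over concentration space,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    boot,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
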