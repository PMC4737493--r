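Package: gsdyn
Title: Ensemble Analysis of Glutamine Synthetase Dynamics, Solvation,
    Energetics, and Rigidity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for conformational ensembles of glutamine
    synthetase (GS) and its disease-linked mutants. Provides multi-model PDB
    input/output with a small atom-selection grammar, least-squares
    superposition, RMSD/RMSF and distance statistics with replicate standard
    errors, hydrogen-bond and salt-bridge occupancies, water density grids,
    radial distribution functions, water-mediated hydrogen-bond bridge
    detection, secondary-structure loop probabilities, effective
    binding-energy aggregation with error propagation and association-constant
    conversions, and body-bar pebble-game rigidity analysis with thermal
    unfolding stability maps. Synthetic-ensemble generators with
    machine-readable ground truth make every stage testable without
    trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
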