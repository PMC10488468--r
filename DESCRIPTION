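Package: memtraj
Title: Membrane-Drug Trajectory Analysis and Conceptual-DFT Reactivity
    Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for molecular-dynamics studies of
    small drug molecules (nucleoside reverse-transcriptase inhibitors)
    interacting with phospholipid monolayers and bilayers. Computes
    partial mass-density profiles along the membrane normal, membrane
    structural metrics (area per lipid, bilayer/monolayer thickness,
    chain order parameters), Einstein-relation diffusion coefficients
    with adsorbed/in-solution classification, geometric hydrogen-bond
    detection and lifetime statistics, CHARMM-style Lennard-Jones and
    Coulomb interaction-energy decompositions, supermolecular complex
    extraction, and conceptual-DFT reactivity descriptors (ionization
    potential, electron affinity, chemical potential, hardness and
    condensed Fukui indices) from tabulated quantum-chemistry output.
    A synthetic-data module generates membrane-like trajectories and
    toy quantum-chemistry tables with known ground truth so that every
    analysis stage is testable without running simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'accessors.R'
    'io.R'
    'synthetic.R'
    'density.R'
    'structure.R'
    'dynamics.R'
    'hbonds.R'
    'energetics.R'
    'reactivity.R'
    'pipeline.R'
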