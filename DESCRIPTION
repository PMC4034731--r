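Package: cvscreen
Title: Consensus Virtual Screening and Molecular Dynamics Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for consensus-based virtual screening of
    small-molecule ligands, built around an FK506-binding protein (FKBP52)
    ligand-discovery case. Computes electrotopological-state (E-state),
    connectivity, polar surface area and shadow descriptors from SMILES/SDF
    input; selects descriptor subsets by Genetic Function Approximation (GFA)
    with a Friedman lack-of-fit penalty; fits multiple linear regression,
    epsilon-support-vector regression and a discretized Bayesian-network
    pIC50 predictor; applies a dock-score gate and rank-threshold consensus
    voting to candidate score tables; profiles protein-ligand interaction
    tables; and computes trajectory summary statistics (RMSD, RMSF, radius
    of gyration, Shrake-Rupley solvent-accessible surface area, hydrogen-bond
    distance series and occupancy, torsion unwrapping, Kabsch-Sander
    secondary structure, GROMOS conformational clustering). Synthetic-data
    generators with planted ground truth make every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    bio3d,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
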