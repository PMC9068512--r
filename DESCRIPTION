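Package: porestates
Title: Conductance-State Analysis of Tetrameric Ion-Channel Gate Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trajectory-analysis toolkit for assigning tetrameric
    ligand-gated ion-channel conformations to discrete conductance states.
    Provides gate-geometry feature extraction (side-chain chi1 dihedrals,
    cross-pore distances, M3 bend angles, pore areas, gate RMSD),
    inscribed-sphere pore-radius profiling with radius-threshold conductance
    classification, directional water/ion permeation counting with
    two-plane hysteresis, unsupervised conformational clustering (t-SNE
    embedding, mean-shift seeding, two-cutoff hierarchical merging,
    circular statistics), weighted-histogram (WHAM) potential-of-mean-force
    estimation with autocorrelation-corrected bootstrap errors, and
    synthetic-data generators with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
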