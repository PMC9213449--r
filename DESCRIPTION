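Package: mtppi
Title: Multi-Task Learning for Protein-Protein Interaction Interface Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of protein-protein interaction (PPI)
    interface residues with a multi-task neural network that learns the
    interface task jointly with related structural tasks (secondary structure
    in three and eight classes, absolute solvent accessibility, buried
    residues) through a masked composite loss, so that proteins lacking PPI
    annotations still contribute through their structural labels. Includes
    structure-derived label generation from multi-chain coordinate files and
    DSSP output (interface contacts by van der Waals distance, buried residues
    by relative accessibility), a 76-dimensional per-residue feature encoder
    (PSSM, HMM profile, physicochemical and rigid-block features), dataset
    assembly with per-protein annotation masking, training with learning-rate
    halving and early stopping on validation interface AUC, evaluation metrics
    with a one-sided independent-AUC test, label-scarcity experiments, and a
    fully self-contained synthetic-data generator for desk-scale runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
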