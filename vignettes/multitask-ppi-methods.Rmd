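---
title: "Multi-task learning for PPI interface prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task learning for PPI interface prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtppi)
```

## The problem

Residues that form protein–protein interaction (PPI) interfaces can be
annotated from experimentally solved complexes, but such annotations exist
for only a minority of structures — roughly one third of a typical
structure-derived training set. Related per-residue structural properties
(secondary structure, solvent accessibility, burial) are available for
essentially every solved structure. `mtppi` implements a multi-task
sequence-labeling strategy that exploits this asymmetry: one shared network
predicts the interface task jointly with the related structural tasks, and a
masked composite loss lets proteins *without* interface annotation still
contribute through their structural labels ("data extension").

## Labels

Per-residue gold standards are derived from structure:

* **IF (interface)** — a residue is an interface residue when any of its
  atoms lies within `r(a) + r(b) + 0.5` Å of an atom in a residue of a
  different chain, with element-wise van der Waals radii (C 1.70, N 1.55,
  O 1.52, S 1.80, P 1.80, Se 1.90, H 1.20 Å; overridable). The label is
  symmetric in the two partner residues. Contacts are computed over the
  atoms present in the file — no hydrogens are inferred, matching the
  X-ray regime the annotation convention comes from. All chains in the
  file are treated as potential partners. Search uses a cell-list spatial
  hash (cell size `2·max(r) + pad`) and is validated against an exhaustive
  all-pairs oracle in the test suite.
* **S8 / S3 (secondary structure)** — eight-state codes from DSSP output
  files; the three-state collapse maps coil/bend/turn to coil, the three
  helix types to helix, and strand/bridge to strand. A blank DSSP structure
  code is coil.
* **SA (absolute solvent accessibility)** — the DSSP ACC field, in Å². A
  built-in Shrake–Rupley routine (92 deterministic sphere points, 1.4 Å
  probe) covers fixtures for which no DSSP output exists.
* **BU (buried)** — `ASA / maxASA(residue) < 0.07`, strictly. The maxASA
  normalisation uses the Tien et al. theoretical maxima. At exact
  floating-point equality with 0.07 the residue is *not* buried (strict
  less-than, the package's convention at the boundary).

Observation masks accompany every label vector: residues with incomplete
side chains (fewer heavy atoms than the residue type's canonical count) are
masked for SA and BU; when a protein carries no PPI annotation its entire
interface vector is masked; masked residues are excluded from losses and
metrics everywhere.

## Input features

Each protein is encoded as an L × 76 matrix: 20 PSSM log-odds columns
(PSI-BLAST ASCII format; raw values by default, a sigmoid option exists),
30 HMM profile columns (HHblits HHM format: 20 match emissions, 7
transition frequencies, 3 Neff diversities, all transformed by
2^(−x/1000) with `*` read as 0, hence in [0, 1]), 7 physicochemical
property columns (the Meiler scales, embedded), and 19 rigid-block
indicator columns (embedded block-composition table). The last two blocks
are pure functions of the residue identity. Unknown residues fall back to
the mean property row and an all-zero block row.

## The masked multi-task loss

With per-task losses L_IF, L_BU, L_S3, L_S8, L_SA the training objective is
their weighted sum. Classification tasks use cross-entropy over per-residue
class probabilities; SA uses squared error. Each task's loss is the mean
over the *unmasked* residues of the batch (not per protein, not a sum):
this keeps the loss scale stable across variable-length batches and makes
the task weights interpretable. Interface positives are up-weighted by the
class-imbalance weight — the ratio of observed non-interface to interface
residues in training plus validation (≈ 6.4 on the default synthetic data),
recomputed per masking configuration by default.

Three weighting schemes are provided, all normalised to total weight 1:
equal weights (**A**); grouped weights (**B**) where similar tasks share one
unit — the default grouping pairs {S3, S8} and {BU, SA}, and an alternative
`pairing = "equation"` pairs {BU, S3} and {S8, SA}, since the two published
descriptions of this scheme are mutually inconsistent and we do not guess
which was run — and an interface-dominant scheme (**C**) where the
interface weight equals the sum of all related-task weights.

## Model and training

The trunk is a sequence-labeling network: dense projection of the 76
features, transformer encoder layers (single-head self-attention with layer
norm and a ReLU feed-forward block), 1-D convolutional layers (kernel 3,
residual), and bidirectional LSTM layers, with one linear head per task
(softmax for classification, identity for SA). The full-size preset uses
2 transformer / 5 CNN / 4 biLSTM layers with dropout 0.25; the `tiny`
preset (1/2/1 layers, width 16, < 200k parameters) is the desk-scale
configuration used throughout the tests and experiments. Internal widths
are package defaults, not normative: the contribution implemented here is
the loss/masking strategy, not the trunk.

The forward pass and analytic backpropagation are implemented in the
package's own C++ engine (RcppArmadillo). There is no dependence on an
external deep-learning framework; correctness of every layer's gradient is
enforced by finite-difference gradient-check tests, and the engine's loss
is cross-checked against an independent pure-R implementation of the
masked composite loss.

Numerical choices worth stating:

* **Ragged batches.** Each protein is processed at its own length and
  batch gradients are averaged, so no padding convention exists to get
  wrong; predictions are bit-identical whether a protein is predicted alone
  or inside a batch. Batch size 4 retains its optimisation meaning.
* **SA scale.** The SA head operates on accessibility × 0.01 (units of
  100 Å²) so the regression loss is commensurate with the cross-entropy
  terms; predictions are always returned in Å². Pearson correlation, the
  SA metric, is scale-invariant.
* **Initialisation** is glorot-uniform (zeros for biases, ones for
  layer-norm gains and LSTM forget-gate biases), fully seeded.
* **Optimiser**: Adam, initial learning rate 2.5e−4, batch size 4.
* **Schedule**: the learning rate halves when the epoch's validation
  interface AUC ROC is *strictly* below the previous epoch's (ties leave it
  unchanged; "previous" is the immediately preceding epoch, not the running
  best); training stops at the fourth such decrease; the checkpoint with
  the best validation interface AUC is retained and reported.
* **Data enhancement**: with probability 0.5 a training protein is
  replaced by a random contiguous fragment (minimum length 30), labels and
  masks cropped consistently.
* Every model is trained four times with seeds `base + 1 … base + 4`; mean
  and sample standard deviation of the best validation interface AUC are
  reported.

Validation and test metrics are micro-averaged over unmasked residues
pooled across proteins; the per-protein error analysis (mean per-protein
interface AUC over repeats against interface size, and ordinary
least-squares R² of related-task scores against interface AUC) is a
separate view, never mixed with the pooled numbers. AUC PR uses the
step-wise average-precision estimator with tied scores processed as one
group. The one-sided comparison of two independent AUCs uses the
Hanley–McNeil standard error and an upper-tail normal p-value; equal AUCs
give exactly p = 0.5.

## The synthetic study conditions

The generator produces data with the statistical structure the method
assumes, so the whole pipeline is exercisable with no downloads:

* a sticky 3-state Markov chain gives realistic secondary-structure runs;
  8-state sub-classes are emitted conditional on the 3-state class;
* relative accessibility is Beta-distributed per class, lower in helix and
  strand than in coil; SA = rsa × maxASA; BU derives from SA by the 7 %
  rule, so labels are mutually consistent by construction;
* residue identities favour hydrophobics at buried positions;
* interface residues are laid down in contiguous patches whose centres are
  drawn with probability ∝ exp(12 × smoothed exposure), at an exact target
  positive fraction of 0.135 (≈ 1 interface per 6.4 non-interface
  residues); one third of the proteins carry interface annotation, the
  rest are interface-masked — the annotation regime the method addresses;
* features carry class signal in the PSSM-like block only: the
  *transferable* signal encodes the shared latent variables (secondary
  structure and exposure), while the interface-specific component uses a
  protein-specific random direction. This mirrors the premise of the
  method: interface conservation signatures are weak and heterogeneous
  across proteins, whereas structural signal is consistent, so a shared
  representation learned from the related tasks is what transfers. Signal
  scales were fixed once so that the full-annotation single-task interface
  AUC lands in the realistic 0.7–0.85 band reported for sequence-based
  interface predictors, and so that the single-task model is clearly
  learnable (validation AUC > 0.6 within 10 epochs).

What the generator does **not** emulate: real conservation profiles (PSSM
columns are Gaussian, not integer log-odds with realistic covariation),
homology between proteins, chain-length and composition biases, unannotated
true interfaces, or physically realistic geometry (the toy complexes place
single-carbon residues with exactly controlled inter-chain distances).
Passing tests therefore demonstrate correctness of the machinery and the
qualitative behaviour of the method under its own assumptions — not
performance on real proteins.

## Problem sizes used by the tests and the acceptance script

The default experiment trains on 300 synthetic proteins of length 40–120
(≈ 100 interface-annotated), tiny preset, up to 30 epochs with early
stopping, four repeats; the label-scarcity experiment compares the
single-task model, the multi-task model, and the multi-task model with
data extension at annotation fractions 1, 1/2 and 1/8, all strategies
sharing the identical (nested) kept-annotation sets and evaluated on the
identical full validation set. These sizes were chosen as the smallest at
which the scarcity effect is stable across seeds.

## Known limitations

* The rigid-block composition table is reconstructed from the block
  definitions rather than copied from the original publication's table;
  the encoding contract (19 binary, residue-determined columns) is what
  downstream code relies on.
* mmCIF support is limited to what `bio3d::read.cif` parses; multi-letter
  chain identifiers are not supported by the toy-complex PDB writer
  (2–62 chains).
* Micro-pooled AUCs treat all validation residues exchangeably; with few
  annotated validation proteins the monitored AUC is noisy, which the
  early-stopping rule inherits.
* The scarcity experiment's conclusions are qualitative (ordering and gap
  growth); absolute AUC values at desk scale are not comparable to results
  on real, large datasets.
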