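# mtppi — multi-task learning for PPI interface prediction

`mtppi` predicts protein–protein interaction (PPI) interface residues from
sequence-derived features with a multi-task neural network, and is built for
the situation that makes this problem hard in practice: residue-level
interface annotations exist for only a minority of proteins (about one
third of structure-derived datasets), while related structural labels —
secondary structure, solvent accessibility, buried residues — exist for
essentially all of them.

The package is aimed at structural bioinformaticians who want to (a) derive
per-residue gold standards from multi-chain structures and DSSP output,
(b) encode proteins as the standard 76-feature representation, and (c)
train and evaluate masked multi-task sequence labelers on partially
annotated data, including the label-scarcity ("data extension")
experiment, at desk scale on a single CPU.

## The method

One shared trunk (transformer → CNN → bidirectional LSTM layers over the
L × 76 feature matrix) feeds one output head per task. Training minimises
the masked composite loss

    L = α·L_IF + β·L_BU + γ·L_S3 + δ·L_S8 + ε·L_SA

where the classification tasks (interface IF, buried BU, 3- and 8-state
secondary structure S3/S8) use cross-entropy, the accessibility regression
SA uses squared error, and every task averages only over residues whose
label is *observed*. A protein with no interface annotation therefore still
trains the shared representation through its structural labels — this is
what lets the model learn from a dataset extended with interface-unlabeled
proteins. Interface positives are up-weighted by the class-imbalance ratio
(non-interface : interface residues, ≈ 6.4 : 1). Labels themselves come
from structure: interface = any inter-chain atom pair closer than the two
van der Waals radii plus 0.5 Å; buried = accessibility below 7 % of the
residue type's maximum; S3/S8/SA from DSSP.

Training follows the published protocol family: Adam at 2.5e−4, batches of
4 proteins, learning-rate halving when the validation interface AUC ROC
drops, early stopping at the fourth drop, best-checkpoint reporting, and a
four-repeat protocol reporting mean ± sd.

## Worked example

Everything below runs from scratch on synthetic data (no downloads):

```r
library(mtppi)
# 300 synthetic proteins; interface annotations on one third of them
records <- generate_dataset(synthetic_params(n_proteins = 300, seed = 42))
pair    <- build_dataset_pair(records)       # PPI subset + extended dataset
splits  <- split_dataset_pair(pair, seed = 42)  # shared 80/10/10 split
cw <- compute_class_weight(c(splits$extended$train, splits$extended$validation))

mt <- repeat_protocol(model_config("tiny", active_tasks = c("IF","BU","S3","SA")),
                      splits$extended$train, splits$extended$validation,
                      weight_scheme("A", c("IF","BU","S3","SA"), if_class_weight = cw),
                      training_config(seed = 1), n_repeats = 4)
st <- repeat_protocol(model_config("tiny", active_tasks = "IF"),
                      splits$ppi$train, splits$ppi$validation,
                      loss_weights(IF = 1, if_class_weight = cw),
                      training_config(seed = 1), n_repeats = 4)
```

Output of this exact script:

```
class imbalance weight: 6.38
single-task IF:        AUC ROC 0.618 +/- 0.038
multi-task IFBUS3SA:   AUC ROC 0.644 +/- 0.031
related tasks (means): BU acc 0.921 | S3 acc 0.626 | SA PCC 0.419
one-sided multi > single p-value: 0.317
```

Read: the single-task interface model reaches validation AUC ROC 0.618 on
the synthetic data; training the same interface task jointly with buried,
3-state secondary structure and accessibility on the extended dataset
(structural labels for all 300 proteins, interface labels for 100) lifts it
to 0.644, with the related tasks themselves predicted well. Desk-scale runs
are deliberately small, so a single comparison is not significant — the
scarcity experiment below aggregates the effect across annotation
fractions.

Label generation from real files works the same way:

```r
s   <- parse_structure("complex.pdb")           # or .cif
ann <- build_annotations(s, parse_dssp("complex.dssp"), ppi_available = TRUE)
write_annotations_tsv(ann, "labels.tsv")
fm  <- encode_protein(sequence, "protein.pssm", "protein.hhm")  # L x 76
```

A thin command-line wrapper for annotation, encoding and synthetic-data
generation is installed at `inst/cli/mtppi`.

## Package tour

| Area | Functions |
|---|---|
| Structure annotation | `parse_structure`, `compute_interface_labels`, `parse_dssp`, `map_s8_to_s3`, `compute_buried_label`, `shrake_rupley_asa`, `build_annotations` |
| Feature encoding | `parse_pssm`, `parse_hhm`, `physchem_features`, `psp19_features`, `encode_protein` |
| Dataset | `protein_record`, `match_ppi_annotations`, `build_dataset_pair`, `split_dataset_pair`, `mask_ppi_fraction`, `compute_class_weight` |
| Loss | `task_loss`, `total_loss`, `multitask_loss`, `weight_scheme`, `loss_weights` |
| Model & training | `model_config`, `build_model`, `predict_mtppi`, `augment_batch`, `train_model`, `repeat_protocol`, `lr_step`, `early_stop` |
| Evaluation | `auc_roc`, `auc_pr`, `threshold_metrics`, `pcc`, `compare_auc_one_sided`, `metrics_report`, `per_protein_analysis` |
| Experiments | `experiment_plan`, `run_task_sweep`, `run_scarcity_curve`, `variant_name` |
| Synthetic data | `synthetic_params`, `generate_dataset`, `generate_toy_complex`, `write_records` |

The methods vignette (`vignettes/multitask-ppi-methods.Rmd`) documents the
models, masking semantics, numerical conventions, the synthetic study
conditions and their limitations.
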