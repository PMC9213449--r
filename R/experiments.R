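# Comparative experiment designs: the task-combination sweep (single-task
# interface model vs multi-task variants on the PPI and extended datasets)
# and the label-scarcity curve (fractions of retained PPI annotations,
# with and without structural-feature data extension). Every strategy at a
# given fraction trains on the identical kept-annotation protein set, and
# evaluation always uses the full validation set.

#' Canonical model-variant name from a task subset
#'
#' Concatenates the task codes in the fixed order IF, BU, S3, S8, SA, so
#' e.g. tasks IF+BU+SA give `"IFBUSA"`.
#'
#' @param tasks Character vector of task codes (must contain `"IF"`).
#' @return Single string.
#' @export
variant_name <- function(tasks) {
  stopifnot("IF" %in% tasks)
  paste(TASK_NAMES[TASK_NAMES %in% tasks], collapse = "")
}

#' Experiment plan
#'
#' @param variants List of task subsets (each containing `"IF"`); defaults
#'   to the single-task baseline and the four-task multi-task model.
#' @param datasets Which dataset(s) to train on: `"ppi"`, `"extended"` or
#'   both.
#' @param keep_fractions Fractions of PPI annotations retained for the
#'   scarcity curve.
#' @param n_repeats Training repeats per cell (default 4).
#' @param base_seed Base seed; repeat r uses `base_seed + r`.
#' @param weight_method Task-weighting scheme, see [weight_scheme()].
#' @param preset Model preset (default `"tiny"`).
#' @param training A [training_config()] template.
#' @return An `experiment_plan` list.
#' @export
experiment_plan <- function(variants = list(c("IF"), c("IF", "BU", "S3", "SA")),
                            datasets = c("ppi", "extended"),
                            keep_fractions = c(1, 1 / 2, 1 / 8),
                            n_repeats = 4L, base_seed = 1L,
                            weight_method = "A", preset = "tiny",
                            training = training_config()) {
  datasets <- match.arg(datasets, c("ppi", "extended"), several.ok = TRUE)
  stopifnot(all(vapply(variants, function(v) "IF" %in% v, logical(1))),
            all(keep_fractions > 0), all(keep_fractions <= 1))
  structure(list(variants = variants, datasets = datasets,
                 keep_fractions = keep_fractions,
                 n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed),
                 weight_method = weight_method, preset = preset,
                 training = training),
            class = "experiment_plan")
}

fit_cell <- function(tasks, train_records, val_records, plan) {
  cw <- compute_class_weight(c(train_records, val_records))
  weights <- if (length(tasks) == 1L) loss_weights(IF = 1, if_class_weight = cw)
             else weight_scheme(plan$weight_method, tasks, if_class_weight = cw)
  cfg <- model_config(plan$preset, active_tasks = tasks)
  tc <- plan$training
  tc$seed <- plan$base_seed
  repeat_protocol(cfg, train_records, val_records, weights, tc,
                  n_repeats = plan$n_repeats,
                  seeds = plan$base_seed + seq_len(plan$n_repeats))
}

#' Task-combination sweep
#'
#' Trains every planned model variant on every planned dataset with the
#' repeat protocol and reports mean and standard deviation of the best
#' validation interface AUC ROC and AUC PR, plus a one-sided significance
#' test of each variant against the single-task baseline on the same
#' dataset.
#'
#' @param plan An [experiment_plan()].
#' @param splits Output of [split_dataset_pair()].
#' @return data.frame with one row per (variant, dataset).
#' @export
run_task_sweep <- function(plan, splits) {
  rows <- list()
  baselines <- list()
  for (ds in plan$datasets) {
    split <- splits[[ds]]
    for (v in plan$variants) {
      res <- fit_cell(v, split$train, split$validation, plan)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = variant_name(v), dataset = ds,
        mean_auc_roc = res$mean[["best_val_auc"]],
        sd_auc_roc = res$sd[["best_val_auc"]],
        mean_auc_pr = res$mean[["if_auc_pr"]],
        sd_auc_pr = res$sd[["if_auc_pr"]],
        n_repeats = plan$n_repeats,
        n_pos = res$pooled_counts[["n_pos"]],
        n_neg = res$pooled_counts[["n_neg"]])
      if (variant_name(v) == "IF") baselines[[ds]] <- rows[[length(rows)]]
    }
  }
  tab <- do.call(rbind, rows)
  tab$p_vs_single_task <- vapply(seq_len(nrow(tab)), function(i) {
    b <- baselines[[tab$dataset[i]]]
    if (is.null(b) || tab$variant[i] == "IF") return(NA_real_)
    compare_auc_one_sided(tab$mean_auc_roc[i], tab$n_pos[i], tab$n_neg[i],
                          b$mean_auc_roc, b$n_pos, b$n_neg)$p_value
  }, numeric(1))
  tab
}

mask_to_kept_ids <- function(records, kept_ids) {
  for (i in seq_along(records)) {
    if (ppi_annotated(records[[i]]) &&
        !(records[[i]]$protein_id %in% kept_ids))
      records[[i]]$masks$IF <- rep(FALSE, nchar(records[[i]]$sequence))
  }
  records
}

#' Label-scarcity curve
#'
#' For each retained-annotation fraction, trains three strategies on the
#' *identical* kept set of PPI-annotated training proteins: the single-task
#' interface model on the PPI dataset, the multi-task model on the PPI
#' dataset, and the multi-task model on the extended dataset (structural
#' labels for all proteins, interface labels only for the kept set). All
#' strategies are evaluated on the full validation set, which is identical
#' across fractions. Kept sets are nested across fractions under the plan's
#' seed.
#'
#' @param plan An [experiment_plan()]; the first multi-task variant in
#'   `plan$variants` defines the multi-task task set.
#' @param splits Output of [split_dataset_pair()].
#' @return List with `results` (data.frame: `fraction`, `strategy`,
#'   `mean_auc`, `sd_auc`, `n_repeats`, `n_kept`) and `kept_ids` (per
#'   fraction).
#' @export
run_scarcity_curve <- function(plan, splits) {
  mt_tasks <- plan$variants[[which(vapply(plan$variants, length, 1L) > 1L)[1]]]
  rows <- list()
  kept_by_fraction <- list()
  for (f in plan$keep_fractions) {
    masked_ext <- mask_ppi_fraction(splits$extended$train, f,
                                    seed = plan$base_seed)
    kept <- masked_ext$kept_ids
    kept_by_fraction[[as.character(f)]] <- kept
    ext_train <- masked_ext$records
    ppi_train <- mask_to_kept_ids(splits$ppi$train, kept)
    # single-task training only sees proteins with observed interface labels
    st_train <- ppi_train[vapply(ppi_train, ppi_annotated, logical(1))]
    cells <- list(
      single_task_ppi = list(tasks = "IF", train = st_train,
                             val = splits$ppi$validation),
      multi_task_ppi = list(tasks = mt_tasks, train = ppi_train,
                            val = splits$ppi$validation),
      multi_task_extended = list(tasks = mt_tasks, train = ext_train,
                                 val = splits$extended$validation))
    for (nm in names(cells)) {
      cell <- cells[[nm]]
      res <- fit_cell(cell$tasks, cell$train, cell$val, plan)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, strategy = nm,
        mean_auc = res$mean[["best_val_auc"]],
        sd_auc = res$sd[["best_val_auc"]],
        n_repeats = plan$n_repeats, n_kept = length(kept))
    }
  }
  list(results = do.call(rbind, rows), kept_ids = kept_by_fraction)
}
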