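# The masked multi-task cost function: per-task losses (cross-entropy for
# the classification tasks IF/BU/S3/S8, mean squared error for SA) averaged
# over unmasked residues only, combined linearly with task weights. Proteins
# or residues without an observed label for a task contribute nothing to that
# task's loss.

TASK_NAMES <- c("IF", "BU", "S3", "S8", "SA")
TASK_NCLASS <- c(IF = 2L, BU = 2L, S3 = 3L, S8 = 8L, SA = 1L)

#' Task weights of the composite multi-task loss
#'
#' The composite loss is `w_IF * L_IF + w_BU * L_BU + w_S3 * L_S3 +
#' w_S8 * L_S8 + w_SA * L_SA`; tasks absent from the active model carry
#' weight exactly 0. `if_class_weight` multiplies the loss terms of observed
#' positive (interface) residues in `L_IF` to counter class imbalance.
#'
#' @param IF,BU,S3,S8,SA Non-negative task weights.
#' @param if_class_weight Positive multiplier on interface-positive loss
#'   terms (default 1).
#' @return A `loss_weights` object.
#' @export
loss_weights <- function(IF = 0, BU = 0, S3 = 0, S8 = 0, SA = 0,
                         if_class_weight = 1) {
  w <- c(IF = IF, BU = BU, S3 = S3, S8 = S8, SA = SA)
  if (any(w < 0) || any(!is.finite(w))) stop("task weights must be finite and non-negative")
  if (all(w == 0)) stop("at least one task weight must be positive")
  if (!is.finite(if_class_weight) || if_class_weight <= 0)
    stop("if_class_weight must be positive")
  structure(list(weights = w, if_class_weight = if_class_weight),
            class = "loss_weights")
}

#' @export
print.loss_weights <- function(x, ...) {
  act <- x$weights[x$weights > 0]
  cat("<loss_weights>", paste(sprintf("%s=%.4g", names(act), act), collapse = " "),
      sprintf("| IF class weight %.4g\n", x$if_class_weight))
  invisible(x)
}

check_probs <- function(p) {
  if (any(!is.finite(p))) stop("non-finite prediction")
  if (any(p < 0 | p > 1)) stop("classification prediction outside [0, 1]")
}

#' Masked per-task loss
#'
#' Mean over unmasked residues of the task's per-residue loss:
#' cross-entropy for the classification tasks (with observed interface
#' positives scaled by `if_class_weight` for task `IF`), squared error for
#' `SA`. Returns 0 when the mask is all-false.
#'
#' @param predictions For classification tasks an `L x K` matrix of class
#'   probabilities (rows sum to 1; K = 2 for IF/BU, 3 for S3, 8 for S8);
#'   for `SA` a numeric vector.
#' @param targets For IF/BU a 0/1 vector; for S3/S8 integer class indices
#'   (1-based); for SA a numeric vector. Values at masked positions are
#'   ignored (may be `NA`).
#' @param mask Logical vector, `TRUE` = observed.
#' @param task One of `"IF"`, `"BU"`, `"S3"`, `"S8"`, `"SA"`.
#' @param if_class_weight Positive-class weight applied for task `"IF"`.
#' @param eps Probability floor inside the logarithm.
#' @return Scalar loss.
#' @export
task_loss <- function(predictions, targets, mask, task,
                      if_class_weight = 1, eps = 1e-12) {
  task <- match.arg(task, TASK_NAMES)
  mask <- as.logical(mask)
  n_obs <- sum(mask)
  if (n_obs == 0L) return(0)
  if (task == "SA") {
    p <- as.numeric(predictions)
    stopifnot(length(p) == length(mask), length(targets) == length(mask))
    if (any(!is.finite(p[mask]))) stop("non-finite prediction")
    return(mean((p[mask] - targets[mask])^2))
  }
  K <- TASK_NCLASS[[task]]
  stopifnot(is.matrix(predictions), ncol(predictions) == K,
            nrow(predictions) == length(mask))
  check_probs(predictions[mask, , drop = FALSE])
  cls <- if (task %in% c("IF", "BU")) as.integer(targets) + 1L else as.integer(targets)
  idx <- which(mask)
  p_true <- predictions[cbind(idx, cls[idx])]
  ce <- -log(pmax(p_true, eps))
  if (task == "IF" && if_class_weight != 1)
    ce <- ce * ifelse(cls[idx] == 2L, if_class_weight, 1)
  mean(ce)
}

#' Combine per-task losses into the total multi-task loss
#'
#' Linear combination of the per-task losses with the task weights. A weight
#' may only be positive for a task whose loss is supplied (active task).
#'
#' @param task_losses Named list/vector of scalar per-task losses; names from
#'   `IF`, `BU`, `S3`, `S8`, `SA`.
#' @param weights A [loss_weights()] object.
#' @return Scalar total loss.
#' @export
total_loss <- function(task_losses, weights) {
  stopifnot(inherits(weights, "loss_weights"))
  tl <- unlist(task_losses)
  extra <- setdiff(names(weights$weights)[weights$weights > 0], names(tl))
  if (length(extra))
    stop("positive weight for inactive task(s): ", paste(extra, collapse = ", "))
  sum(weights$weights[names(tl)] * tl)
}

#' Per-batch multi-task loss report
#'
#' Computes every active task's masked loss over a batch of proteins, the
#' number of unmasked residue contributions per task, and the weighted total.
#' This is the reference (pure R) implementation of the loss the training
#' engine optimises; a task with zero unmasked residues reports loss 0 and
#' count 0 and contributes nothing.
#'
#' @param predictions Named list (per task) of per-protein prediction lists,
#'   i.e. `predictions$S3[[i]]` is the `L_i x 3` probability matrix of
#'   protein `i`.
#' @param records List of protein records carrying `labels` and `masks`.
#' @param weights A [loss_weights()] object.
#' @return List with `task_losses`, `counts`, `total`.
#' @export
multitask_loss <- function(predictions, records, weights) {
  active <- names(weights$weights)[weights$weights > 0]
  task_losses <- counts <- stats::setNames(numeric(length(active)), active)
  for (task in active) {
    pooled_num <- 0; pooled_cnt <- 0
    for (i in seq_along(records)) {
      m <- records[[i]]$masks[[task]]
      if (!any(m)) next
      l <- task_loss(predictions[[task]][[i]], records[[i]]$labels[[task]], m,
                     task, weights$if_class_weight)
      pooled_num <- pooled_num + l * sum(m)
      pooled_cnt <- pooled_cnt + sum(m)
    }
    task_losses[[task]] <- if (pooled_cnt > 0) pooled_num / pooled_cnt else 0
    counts[[task]] <- pooled_cnt
  }
  list(task_losses = as.list(task_losses), counts = counts,
       total = total_loss(task_losses, weights))
}

#' Task-weighting schemes
#'
#' Three ways to set the relative task weights, all normalised to sum 1:
#' * **A** — all active tasks weighted equally.
#' * **B** — similar tasks are grouped and each group present receives, in
#'   total, the weight of one ungrouped task, split equally within the group
#'   (a group with a single active member keeps the full unit). The default
#'   grouping pairs the secondary-structure tasks \{S3, S8\} and the
#'   accessibility tasks \{BU, SA\}; `pairing = "equation"` instead applies
#'   the constraint reading that pairs \{BU, S3\} and \{S8, SA\}.
#' * **C** — the interface weight equals the sum of all related-task
#'   weights (50 percent of the total), the related tasks weighted equally.
#'
#' @param method `"A"`, `"B"` or `"C"`.
#' @param active_tasks Character vector of active tasks; must contain `"IF"`.
#' @param pairing Method-B grouping, `"similarity"` (default) or
#'   `"equation"`.
#' @param if_class_weight Passed through to [loss_weights()].
#' @return A [loss_weights()] object with weights summing to 1 over the
#'   active tasks.
#' @export
weight_scheme <- function(method = c("A", "B", "C"), active_tasks,
                          pairing = c("similarity", "equation"),
                          if_class_weight = 1) {
  method <- match.arg(method)
  pairing <- match.arg(pairing)
  active_tasks <- match.arg(active_tasks, TASK_NAMES, several.ok = TRUE)
  if (!"IF" %in% active_tasks) stop("the interface task IF must be active")
  units <- stats::setNames(numeric(length(active_tasks)), active_tasks)
  if (method == "A") {
    units[] <- 1
  } else if (method == "B") {
    groups <- if (pairing == "similarity") list(c("S3", "S8"), c("BU", "SA"))
              else list(c("BU", "S3"), c("S8", "SA"))
    units[] <- 1
    for (g in groups) {
      present <- intersect(g, active_tasks)
      if (length(present) == 2L) units[present] <- 0.5
    }
  } else {
    related <- setdiff(active_tasks, "IF")
    if (length(related) == 0L) stop("method C needs at least one related task")
    units[related] <- 1 / length(related)
    units["IF"] <- 1
  }
  units <- units / sum(units)
  w <- stats::setNames(rep(0, 5), TASK_NAMES)
  w[names(units)] <- units
  loss_weights(IF = w[["IF"]], BU = w[["BU"]], S3 = w[["S3"]],
               S8 = w[["S8"]], SA = w[["SA"]], if_class_weight = if_class_weight)
}
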