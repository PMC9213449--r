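# Performance measures over unmasked residues: threshold-free ranking
# metrics (AUC ROC, AUC PR), fixed-threshold classification metrics at 0.5,
# Pearson correlation for the accessibility regression, a one-sided
# significance test for two independent AUCs, and the per-protein error
# analysis.

apply_mask <- function(scores, labels, mask) {
  mask <- as.logical(mask)
  list(s = scores[mask], y = labels[mask])
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator: the probability that a positive
#' residue receives a higher score than a negative one, ties counting one
#' half. Computed over unmasked residues only.
#'
#' @param scores Numeric prediction scores (higher = more interface-like).
#' @param labels 0/1 labels.
#' @param mask Logical observation mask (default all observed).
#' @return AUC in [0, 1]; `NA` with a warning when either class is absent
#'   among unmasked residues.
#' @export
auc_roc <- function(scores, labels, mask = rep(TRUE, length(scores))) {
  d <- apply_mask(scores, labels, mask)
  n_pos <- sum(d$y == 1); n_neg <- sum(d$y == 0)
  if (n_pos == 0 || n_neg == 0) {
    warning("AUC ROC undefined: need at least one positive and one negative")
    return(NA_real_)
  }
  r <- rank(d$s, ties.method = "average")
  (sum(r[d$y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise estimator (average precision): precision is evaluated at each
#' distinct score threshold and weighted by the recall gained there, with
#' tied scores processed as one group.
#'
#' @inheritParams auc_roc
#' @return AUC PR in [0, 1]; `NA` with a warning when no positive is
#'   observed.
#' @export
auc_pr <- function(scores, labels, mask = rep(TRUE, length(scores))) {
  d <- apply_mask(scores, labels, mask)
  n_pos <- sum(d$y == 1)
  if (n_pos == 0) {
    warning("AUC PR undefined: no observed positives")
    return(NA_real_)
  }
  ord <- order(d$s, decreasing = TRUE)
  s <- d$s[ord]; y <- d$y[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  tp <- cumsum(tp_g); n_cum <- cumsum(n_g)
  prec <- tp / n_cum
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Fixed-threshold classification metrics
#'
#' Accuracy, precision, recall, specificity, F1 and the Matthews correlation
#' coefficient at the classification threshold 0.5, over unmasked residues.
#' Undefined ratios (empty denominators) are returned as `NA`.
#'
#' @inheritParams auc_roc
#' @param threshold Score cut for calling a positive (default 0.5).
#' @return Named list with `acc`, `precision`, `recall`, `specificity`,
#'   `f1`, `mcc` and the confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
threshold_metrics <- function(scores, labels, mask = rep(TRUE, length(scores)),
                              threshold = 0.5) {
  d <- apply_mask(scores, labels, mask)
  pred <- as.integer(d$s >= threshold)
  tp <- sum(pred == 1 & d$y == 1); fp <- sum(pred == 1 & d$y == 0)
  fn <- sum(pred == 0 & d$y == 1); tn <- sum(pred == 0 & d$y == 0)
  sdiv <- function(a, b) if (b > 0) a / b else NA_real_
  prec <- sdiv(tp, tp + fp); rec <- sdiv(tp, tp + fn)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(acc = sdiv(tp + tn, tp + fp + fn + tn),
       precision = prec, recall = rec,
       specificity = sdiv(tn, tn + fp),
       f1 = if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
         2 * prec * rec / (prec + rec) else NA_real_,
       mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Multi-class accuracy over unmasked residues
#'
#' @param pred_class Predicted class indices (argmax of the head's
#'   probabilities).
#' @param target_class True class indices.
#' @param mask Logical observation mask.
#' @return Fraction of unmasked residues predicted correctly.
#' @export
class_accuracy <- function(pred_class, target_class,
                           mask = rep(TRUE, length(pred_class))) {
  mask <- as.logical(mask)
  if (!any(mask)) return(NA_real_)
  mean(pred_class[mask] == target_class[mask])
}

#' Pearson correlation over unmasked residues
#'
#' @param pred,target Numeric vectors (e.g. predicted and true absolute
#'   solvent accessibility).
#' @param mask Logical observation mask.
#' @return PCC in [-1, 1]; `NA` with a warning for fewer than two unmasked
#'   pairs or zero variance.
#' @export
pcc <- function(pred, target, mask = rep(TRUE, length(pred))) {
  mask <- as.logical(mask)
  p <- pred[mask]; t <- target[mask]
  if (length(p) < 2 || stats::sd(p) == 0 || stats::sd(t) == 0) {
    warning("PCC undefined: need >= 2 unmasked pairs with nonzero variance")
    return(NA_real_)
  }
  stats::cor(p, t)
}

hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' One-sided test for two independent AUC ROC scores
#'
#' Tests whether `auc1` exceeds `auc2` using the normal approximation
#' `z = (auc1 - auc2) / sqrt(SE1^2 + SE2^2)` with the Hanley-McNeil
#' standard error for each AUC; returns the upper-tail p-value. Equal AUCs
#' give exactly p = 0.5.
#'
#' @param auc1,auc2 The two AUC ROC values in [0, 1].
#' @param n_pos1,n_neg1,n_pos2,n_neg2 Positive/negative counts underlying
#'   each AUC.
#' @return List with `z`, `p_value`, `se1`, `se2`.
#' @export
compare_auc_one_sided <- function(auc1, n_pos1, n_neg1, auc2, n_pos2, n_neg2) {
  stopifnot(auc1 >= 0, auc1 <= 1, auc2 >= 0, auc2 <= 1)
  if (min(n_pos1, n_neg1, n_pos2, n_neg2) <= 0)
    stop("positive and negative counts must be > 0")
  se1 <- hanley_mcneil_se(auc1, n_pos1, n_neg1)
  se2 <- hanley_mcneil_se(auc2, n_pos2, n_neg2)
  z <- (auc1 - auc2) / sqrt(se1^2 + se2^2)
  list(z = z, p_value = stats::pnorm(z, lower.tail = FALSE), se1 = se1, se2 = se2)
}

#' Full metric report for model predictions on a record set
#'
#' Micro-averaged over unmasked residues pooled across proteins: interface
#' metrics (AUC ROC, AUC PR, threshold metrics), BU/S3/S8 accuracy and SA
#' Pearson correlation, for whichever tasks the prediction list carries.
#'
#' @param predictions Per-task list of per-protein predictions as returned
#'   by [predict_mtppi()].
#' @param records The protein records predicted on.
#' @return Nested list task -> metric -> value, plus `counts` of evaluated
#'   residues per task.
#' @export
metrics_report <- function(predictions, records) {
  pool <- function(task, what = c("score", "class", "value")) {
    what <- match.arg(what)
    s <- y <- m <- NULL
    for (i in seq_along(records)) {
      pr <- predictions[[task]][[i]]
      v <- switch(what,
                  score = pr[, 2],
                  class = max.col(pr),
                  value = as.numeric(pr))
      s <- c(s, v)
      y <- c(y, records[[i]]$labels[[task]])
      m <- c(m, records[[i]]$masks[[task]])
    }
    list(s = s, y = y, m = as.logical(m))
  }
  out <- list(counts = list())
  for (task in names(predictions)) {
    if (task %in% c("IF", "BU")) {
      d <- pool(task, "score")
      out[[task]] <- c(list(auc_roc = if (any(d$m)) auc_roc(d$s, d$y, d$m) else NA_real_,
                            auc_pr = if (any(d$m)) auc_pr(d$s, d$y, d$m) else NA_real_),
                       if (any(d$m)) threshold_metrics(d$s, d$y, d$m) else list())
    } else if (task %in% c("S3", "S8")) {
      d <- pool(task, "class")
      out[[task]] <- list(acc = class_accuracy(d$s, d$y, d$m))
    } else {
      d <- pool(task, "value")
      out[[task]] <- list(pcc = if (sum(d$m) >= 2) pcc(d$s, d$y, d$m) else NA_real_,
                          mse = if (any(d$m)) mean((d$s[d$m] - d$y[d$m])^2) else NA_real_)
    }
    out$counts[[task]] <- sum(pool(task, if (task == "SA") "value" else "score")$m)
  }
  out
}

#' Per-protein error analysis
#'
#' For each test protein, the interface AUC ROC averaged over repeated
#' training runs, the observed interface size, and the related-task scores
#' (BU accuracy, S3 accuracy, SA Pearson correlation); proteins whose
#' unmasked interface labels lack a positive or a negative carry an
#' undefined-AUC flag and are excluded from the regressions. Each
#' related-task score is regressed on the mean interface AUC by ordinary
#' least squares and the R-squared reported.
#'
#' @param predictions_over_repeats List (one per repeat) of per-task
#'   prediction lists on the same records.
#' @param records The test protein records.
#' @return List with `table` (one row per protein: `protein_id`,
#'   `n_interface`, `auc_defined`, `mean_if_auc`, `bu_acc`, `s3_acc`,
#'   `sa_pcc`) and `r_squared` (named: `bu_acc`, `s3_acc`, `sa_pcc`).
#' @export
per_protein_analysis <- function(predictions_over_repeats, records) {
  stopifnot(length(predictions_over_repeats) >= 2)
  n <- length(records)
  rows <- lapply(seq_len(n), function(i) {
    rec <- records[[i]]
    m <- as.logical(rec$masks$IF)
    y <- rec$labels$IF
    n_if <- sum(m & y == 1, na.rm = TRUE)
    defined <- any(m & y == 1, na.rm = TRUE) && any(m & y == 0, na.rm = TRUE)
    aucs <- if (defined) vapply(predictions_over_repeats, function(p)
      auc_roc(p$IF[[i]][, 2], y, m), numeric(1)) else NA_real_
    rel <- function(task, fun) {
      mm <- as.logical(rec$masks[[task]])
      if (!any(mm)) return(NA_real_)
      mean(vapply(predictions_over_repeats, function(p) fun(p, mm), numeric(1)))
    }
    data.frame(protein_id = rec$protein_id, n_interface = n_if,
               auc_defined = defined, mean_if_auc = mean(aucs),
               bu_acc = rel("BU", function(p, mm)
                 class_accuracy(as.integer(p$BU[[i]][, 2] >= 0.5),
                                rec$labels$BU, mm)),
               s3_acc = rel("S3", function(p, mm)
                 class_accuracy(max.col(p$S3[[i]]), rec$labels$S3, mm)),
               sa_pcc = rel("SA", function(p, mm)
                 suppressWarnings(pcc(as.numeric(p$SA[[i]]), rec$labels$SA, mm))),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  r2 <- vapply(c("bu_acc", "s3_acc", "sa_pcc"), function(col) {
    ok <- tab$auc_defined & !is.na(tab[[col]])
    if (sum(ok) < 3) return(NA_real_)
    summary(stats::lm(tab[[col]][ok] ~ tab$mean_if_auc[ok]))$r.squared
  }, numeric(1))
  list(table = tab, r_squared = r2)
}
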