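# Training loop: Adam at initial learning rate 2.5e-4, batches of 4
# proteins, per-epoch validation monitored by the interface AUC ROC,
# learning-rate halving whenever the monitored AUC drops below the previous
# epoch's value, early stopping at the fourth such decrease, and the
# four-repeat protocol reporting mean and standard deviation.

#' Training configuration
#'
#' @param initial_lr Initial Adam learning rate (default 2.5e-4).
#' @param batch_size Proteins per batch (default 4).
#' @param max_epochs Upper bound on epochs (default 30); early stopping
#'   usually fires first.
#' @param seed Base seed controlling initialisation, shuffling, enhancement
#'   and dropout.
#' @param enhance Apply fragment enhancement to training batches.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters.
#' @return A `training_config` list.
#' @export
training_config <- function(initial_lr = 2.5e-4, batch_size = 4L,
                            max_epochs = 30L, seed = 1L, enhance = TRUE,
                            adam_beta1 = 0.9, adam_beta2 = 0.999,
                            adam_eps = 1e-8) {
  stopifnot(initial_lr > 0, batch_size >= 1)
  structure(list(initial_lr = initial_lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 enhance = enhance, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_eps = adam_eps),
            class = "training_config")
}

#' Learning-rate schedule step
#'
#' The learning rate is divided by two exactly when the current epoch's
#' validation interface AUC ROC is strictly lower than the previous
#' epoch's; ties and improvements leave it unchanged.
#'
#' @param val_aucs Numeric vector of per-epoch validation AUC ROC values so
#'   far (most recent last).
#' @param current_lr The learning rate in effect.
#' @return The learning rate for the next epoch.
#' @export
lr_step <- function(val_aucs, current_lr) {
  n <- length(val_aucs)
  if (n < 2) return(current_lr)
  if (val_aucs[n] < val_aucs[n - 1]) current_lr / 2 else current_lr
}

count_decreases <- function(val_aucs) sum(diff(val_aucs) < 0)

#' Early-stopping criterion
#'
#' Training converges when, for the fourth time, the validation interface
#' AUC ROC is strictly lower than the immediately preceding epoch's value.
#'
#' @param val_aucs Per-epoch validation AUC ROC values so far.
#' @param patience Number of decreases that triggers the stop (default 4).
#' @return `TRUE` exactly when the cumulative decrease count has reached
#'   `patience`.
#' @export
early_stop <- function(val_aucs, patience = 4L) {
  count_decreases(val_aucs) >= patience
}

adam_step <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + cfg$adam_eps)
  }
  list(params = params, state = state)
}

val_if_auc <- function(model, val_records) {
  preds <- predict_mtppi(model, val_records)
  s <- y <- m <- NULL
  for (i in seq_along(val_records)) {
    s <- c(s, preds$IF[[i]][, 2])
    y <- c(y, val_records[[i]]$labels$IF)
    m <- c(m, val_records[[i]]$masks$IF)
  }
  if (!any(as.logical(m))) stop("validation set has no observed interface labels")
  list(auc = auc_roc(s, y, as.logical(m)), preds = preds)
}

#' Train a multi-task model
#'
#' Runs the full loop: shuffled batches with optional fragment enhancement,
#' Adam updates of the masked multi-task loss, a validation pass per epoch
#' computing all active-task metrics, learning-rate halving on validation
#' AUC decrease and early stopping at the fourth decrease. The checkpoint
#' with the highest validation interface AUC ROC is retained and returned.
#' Fully deterministic under `config$seed`.
#'
#' @param model An `mtppi_model` (freshly built or warm).
#' @param train_records,val_records Protein record lists.
#' @param weights A [loss_weights()] object over the model's active tasks.
#' @param config A [training_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best checkpoint), `history` (data.frame:
#'   `epoch`, `train_loss`, `val_if_auc`, `lr`, `n_decreases`),
#'   `best_epoch`, `best_val_auc`, `best_metrics` (full [metrics_report()]
#'   at the best epoch).
#' @export
train_model <- function(model, train_records, val_records, weights,
                        config = training_config(), verbose = FALSE) {
  active <- names(weights$weights)[weights$weights > 0]
  if (!all(active %in% model$config$tasks))
    stop("positive weight for task(s) not in the model: ",
         paste(setdiff(active, model$config$tasks), collapse = ", "))
  params <- model$params
  state <- list(t = 0L, m = list(), v = list())
  lr <- config$initial_lr
  history <- data.frame()
  val_aucs <- numeric(0)
  best <- list(auc = -Inf, params = params, epoch = 0L, metrics = NULL)
  n <- length(train_records)
  epoch_seeds <- run_seeded(config$seed, sample.int(2^30, config$max_epochs))
  for (epoch in seq_len(config$max_epochs)) {
    epoch_info <- run_seeded(epoch_seeds[epoch], {
      ord <- sample(n)
      aug_seed <- sample.int(2^30, 1)
      drop_seeds <- sample.int(2^30, ceiling(n / config$batch_size))
      list(ord = ord, aug_seed = aug_seed, drop_seeds = drop_seeds)
    })
    recs <- train_records[epoch_info$ord]
    if (config$enhance)
      recs <- augment_batch(recs, model$config, seed = epoch_info$aug_seed)
    starts <- seq(1, n, by = config$batch_size)
    epoch_loss <- 0
    for (bi in seq_along(starts)) {
      idx <- starts[bi]:min(starts[bi] + config$batch_size - 1L, n)
      model$params <- params
      out <- model_loss_grad(model, recs[idx], weights, training = TRUE,
                             dropout_seed = epoch_info$drop_seeds[bi])
      if (!is.finite(out$total))
        stop("training diverged: non-finite loss at epoch ", epoch,
             ", batch ", bi)
      upd <- adam_step(params, out$grads, state, lr, config)
      params <- upd$params; state <- upd$state
      epoch_loss <- epoch_loss + out$total
    }
    model$params <- params
    v <- val_if_auc(model, val_records)
    val_aucs <- c(val_aucs, v$auc)
    if (is.finite(v$auc) && v$auc > best$auc) {
      best$auc <- v$auc; best$params <- params; best$epoch <- epoch
      best$metrics <- metrics_report(v$preds, val_records)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / length(starts),
      val_if_auc = v$auc, lr = lr, n_decreases = count_decreases(val_aucs)))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val IF AUC %.4f, lr %.2e",
                      epoch, epoch_loss / length(starts), v$auc, lr))
    if (early_stop(val_aucs)) break
    lr <- lr_step(val_aucs, lr)
  }
  model$params <- best$params
  list(model = model, history = history, best_epoch = best$epoch,
       best_val_auc = best$auc, best_metrics = best$metrics)
}

#' Repeated-training protocol
#'
#' Trains the same configuration `n_repeats` times with independent seeds
#' (`base_seed + repeat index`), then reports the sample mean and standard
#' deviation of the best validation interface AUC ROC together with the
#' related-task metrics at each run's best checkpoint.
#'
#' @param config A [model_config()].
#' @param train_records,val_records Protein record lists.
#' @param weights A [loss_weights()] object.
#' @param training_cfg A [training_config()]; its seed is the base seed.
#' @param n_repeats Number of repeats (default 4).
#' @param seeds Optional explicit seeds (length `n_repeats`); duplicated
#'   seeds trigger a degenerate-protocol warning.
#' @return List with `per_repeat` (data.frame of per-run best metrics),
#'   `mean`, `sd` (named vectors), `pooled_counts` (positives/negatives in
#'   the monitored validation AUC).
#' @export
repeat_protocol <- function(config, train_records, val_records, weights,
                            training_cfg = training_config(), n_repeats = 4L,
                            seeds = NULL) {
  stopifnot(n_repeats >= 2)
  if (is.null(seeds)) seeds <- training_cfg$seed + seq_len(n_repeats)
  if (anyDuplicated(seeds))
    warning("duplicated repeat seeds: repeats are not independent, sd degenerate")
  rows <- lapply(seeds, function(s) {
    tc <- training_cfg; tc$seed <- as.integer(s)
    model <- build_model(config, seed = s)
    fit <- train_model(model, train_records, val_records, weights, tc)
    mr <- fit$best_metrics
    data.frame(seed = s, best_val_auc = fit$best_val_auc,
               best_epoch = fit$best_epoch,
               if_auc_pr = if (!is.null(mr$IF$auc_pr)) mr$IF$auc_pr else NA_real_,
               bu_acc = if (!is.null(mr$BU$acc)) mr$BU$acc else NA_real_,
               s3_acc = if (!is.null(mr$S3$acc)) mr$S3$acc else NA_real_,
               s8_acc = if (!is.null(mr$S8$acc)) mr$S8$acc else NA_real_,
               sa_pcc = if (!is.null(mr$SA$pcc)) mr$SA$pcc else NA_real_)
  })
  per_repeat <- do.call(rbind, rows)
  num <- per_repeat[, setdiff(names(per_repeat), "seed"), drop = FALSE]
  y <- m <- NULL
  for (r in val_records) { y <- c(y, r$labels$IF); m <- c(m, r$masks$IF) }
  m <- as.logical(m)
  list(per_repeat = per_repeat,
       mean = vapply(num, mean, numeric(1), na.rm = TRUE),
       sd = vapply(num, stats::sd, numeric(1), na.rm = TRUE),
       pooled_counts = c(n_pos = sum(m & y == 1, na.rm = TRUE),
                         n_neg = sum(m & y == 0, na.rm = TRUE)))
}
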