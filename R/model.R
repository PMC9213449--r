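# The shared-representation sequence-labeling model: dense input projection
# of the 76 features, transformer encoder layers, 1-D CNN layers and
# bidirectional LSTM layers shared across tasks, with one linear output head
# per active task (softmax for classification, identity for the
# accessibility regression). The numerical engine (forward pass and analytic
# backpropagation) lives in the package's C++ code.

#' Model configuration
#'
#' Architecture settings for the multi-task network. The `"full"` preset
#' follows the published architecture family (2 transformer, 5 CNN and 4
#' bidirectional LSTM layers, dropout 0.25, ReLU activations); internal
#' widths are this package's defaults. The `"tiny"` preset is a desk-scale
#' configuration of the same family (under 200k parameters) for CPU-only
#' experimentation and testing.
#'
#' @param preset `"tiny"` (default) or `"full"`.
#' @param active_tasks Subset of `c("IF","BU","S3","S8","SA")`; every model
#'   predicts the interface task.
#' @param ... Overrides for individual fields: `n_transformer`, `n_cnn`,
#'   `n_birnn`, `d_model`, `ff_dim`, `rnn_hidden`, `dropout`,
#'   `enhance_prob`, `enhance_min_len`, `sa_scale` (the SA head operates on
#'   accessibility times `sa_scale`; default 0.01, i.e. units of 100
#'   angstrom^2, which keeps the regression loss commensurate with the
#'   cross-entropy terms; predictions are always returned in angstrom^2).
#' @return A `model_config` list.
#' @export
model_config <- function(preset = c("tiny", "full"),
                         active_tasks = c("IF", "BU", "S3", "SA"), ...) {
  preset <- match.arg(preset)
  active_tasks <- match.arg(active_tasks, TASK_NAMES, several.ok = TRUE)
  if (!"IF" %in% active_tasks) stop("active_tasks must include IF")
  base <- if (preset == "full") {
    list(n_transformer = 2L, n_cnn = 5L, n_birnn = 4L, d_model = 64L,
         ff_dim = 128L, rnn_hidden = 64L, dropout = 0.25)
  } else {
    list(n_transformer = 1L, n_cnn = 2L, n_birnn = 1L, d_model = 16L,
         ff_dim = 32L, rnn_hidden = 16L, dropout = 0.1)
  }
  cfg <- utils::modifyList(c(base, list(enhance_prob = 0.5,
                                        enhance_min_len = 30L,
                                        sa_scale = 0.01)),
                           list(...))
  cfg$preset <- preset
  cfg$tasks <- active_tasks
  stopifnot(cfg$dropout >= 0, cfg$dropout < 1)
  structure(cfg, class = "model_config")
}

task_head_sizes <- function() TASK_NCLASS

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Build a multi-task model
#'
#' Initialises all parameters (glorot uniform for weights, zeros for biases,
#' ones for layer-norm gains and LSTM forget-gate biases) under the given
#' seed. The trunk parameters are shared by every task head, so each active
#' task's loss backpropagates into the same shared representation.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the initialisation.
#' @return An `mtppi_model`: list with `config` and `params` (named list of
#'   matrices).
#' @export
build_model <- function(config, seed = 1) {
  stopifnot(inherits(config, "model_config"))
  if (length(config$tasks) == 0L) stop("active_tasks must be non-empty")
  d <- config$d_model; f <- config$ff_dim; h <- config$rnn_hidden
  out_dim <- if (config$n_birnn > 0) 2L * h else d
  params <- run_seeded(seed, {
    p <- list(in_W = glorot(76, d), in_b = matrix(0, 1, d))
    for (l in seq_len(config$n_transformer) - 1L) {
      pf <- paste0("t", l, "_")
      p[[paste0(pf, "Wq")]] <- glorot(d, d)
      p[[paste0(pf, "Wk")]] <- glorot(d, d)
      p[[paste0(pf, "Wv")]] <- glorot(d, d)
      p[[paste0(pf, "Wo")]] <- glorot(d, d)
      p[[paste0(pf, "bo")]] <- matrix(0, 1, d)
      p[[paste0(pf, "ln1_g")]] <- matrix(1, 1, d)
      p[[paste0(pf, "ln1_b")]] <- matrix(0, 1, d)
      p[[paste0(pf, "W1")]] <- glorot(d, f)
      p[[paste0(pf, "b1")]] <- matrix(0, 1, f)
      p[[paste0(pf, "W2")]] <- glorot(f, d)
      p[[paste0(pf, "b2")]] <- matrix(0, 1, d)
      p[[paste0(pf, "ln2_g")]] <- matrix(1, 1, d)
      p[[paste0(pf, "ln2_b")]] <- matrix(0, 1, d)
    }
    for (l in seq_len(config$n_cnn) - 1L) {
      pf <- paste0("c", l, "_")
      p[[paste0(pf, "W")]] <- glorot(3 * d, d)
      p[[paste0(pf, "b")]] <- matrix(0, 1, d)
    }
    for (l in seq_len(config$n_birnn) - 1L) {
      n_in <- if (l == 0) d else 2L * h
      for (dir in c("f", "b")) {
        pf <- paste0("l", l, dir, "_")
        p[[paste0(pf, "Wx")]] <- glorot(n_in, 4 * h)
        p[[paste0(pf, "Wh")]] <- glorot(h, 4 * h)
        b <- matrix(0, 1, 4 * h)
        b[1, (h + 1):(2 * h)] <- 1  # forget-gate bias
        p[[paste0(pf, "b")]] <- b
      }
    }
    for (task in config$tasks) {
      K <- task_head_sizes()[[task]]
      p[[paste0("head_", task, "_W")]] <- glorot(out_dim, K)
      p[[paste0("head_", task, "_b")]] <- matrix(0, 1, K)
    }
    p
  })
  structure(list(config = config, params = params), class = "mtppi_model")
}

#' Number of trainable parameters
#' @param model An `mtppi_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 1L))
}

#' @export
print.mtppi_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<mtppi_model> preset %s: %d transformer / %d CNN / %d biLSTM layers, d=%d, h=%d\n",
              cfg$preset, cfg$n_transformer, cfg$n_cnn, cfg$n_birnn,
              cfg$d_model, cfg$rnn_hidden))
  cat(sprintf("  tasks: %s | %d parameters\n", paste(cfg$tasks, collapse = ""),
              n_parameters(x)))
  invisible(x)
}

cfg_for_cpp <- function(config) {
  list(d_model = config$d_model, ff_dim = config$ff_dim,
       n_transformer = config$n_transformer, n_cnn = config$n_cnn,
       n_birnn = config$n_birnn, rnn_hidden = config$rnn_hidden,
       dropout = config$dropout, tasks = config$tasks)
}

record_features <- function(record) {
  if (inherits(record$features, "feature_matrix")) record$features$values
  else record$features
}

#' Model predictions for a set of proteins
#'
#' Deterministic forward pass (dropout disabled). Each protein is processed
#' at its own length, so results do not depend on any padding convention.
#'
#' @param model An `mtppi_model`.
#' @param records List of `protein_record`s (or a single record).
#' @return Named list task -> list of per-protein predictions:
#'   classification heads give `L x K` probability matrices (rows sum to 1),
#'   the SA head an `L x 1` matrix of accessibility predictions.
#' @export
predict_mtppi <- function(model, records) {
  if (inherits(records, "protein_record")) records <- list(records)
  X <- lapply(records, record_features)
  for (x in X) if (ncol(x) != 76) stop("feature dimension must be 76")
  out <- .nn_predict_cpp(model$params, cfg_for_cpp(model$config), X)
  if ("SA" %in% names(out))
    out$SA <- lapply(out$SA, function(m) m / model$config$sa_scale)
  out
}

#' Batch loss and parameter gradients
#'
#' One evaluation of the masked multi-task loss and its gradients over a
#' batch of proteins. Per task, the loss is the mean over the batch's
#' unmasked residues (interface positives scaled by the class weight); the
#' total is the weighted sum over active tasks. Exposed mainly for testing
#' and for the training loop.
#'
#' @param model An `mtppi_model`.
#' @param records List of `protein_record`s.
#' @param weights A [loss_weights()] object over the model's active tasks.
#' @param training Apply dropout when `TRUE`.
#' @param dropout_seed Integer seed for the dropout masks.
#' @return List with `total`, `task_losses`, `counts`, `grads`.
#' @export
model_loss_grad <- function(model, records, weights, training = FALSE,
                            dropout_seed = 0L) {
  active <- names(weights$weights)[weights$weights > 0]
  if (!all(active %in% model$config$tasks))
    stop("positive weight for task(s) not in the model: ",
         paste(setdiff(active, model$config$tasks), collapse = ", "))
  batch <- lapply(records, function(r) {
    lab <- r$labels
    lab$SA <- lab$SA * model$config$sa_scale
    lab <- lapply(lab, function(v) { v[is.na(v)] <- 0; as.numeric(v) })
    list(X = record_features(r), labels = lab,
         masks = lapply(r$masks, as.logical))
  })
  .nn_batch_grad_cpp(model$params, cfg_for_cpp(model$config), batch,
                     weights$weights[model$config$tasks],
                     weights$if_class_weight, training,
                     as.integer(dropout_seed))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is one serialized file (RDS) holding a format version, the
#' model configuration, all parameters, and optionally the training history
#' that produced it.
#'
#' @param model An `mtppi_model`.
#' @param path File path.
#' @param history Optional training history to store alongside.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with `model` and `history`.
#' @export
save_checkpoint <- function(model, path, history = NULL) {
  stopifnot(inherits(model, "mtppi_model"))
  saveRDS(list(format = "mtppi-checkpoint-1", config = model$config,
               params = model$params, history = history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mtppi-checkpoint-1"))
    stop("not an mtppi checkpoint: ", path)
  list(model = structure(list(config = obj$config, params = obj$params),
                         class = "mtppi_model"),
       history = obj$history)
}

crop_record <- function(record, from, to) {
  idx <- from:to
  record$sequence <- substr(record$sequence, from, to)
  record$features <- record_features(record)[idx, , drop = FALSE]
  record$labels <- lapply(record$labels, function(v) v[idx])
  record$masks <- lapply(record$masks, function(v) v[idx])
  record
}

#' Training-time data enhancement by fragment sampling
#'
#' With probability `config$enhance_prob`, a training protein is replaced by
#' a random contiguous fragment of itself (uniform length between
#' `config$enhance_min_len` and the full length, uniform start); labels and
#' masks are cropped to the same window. Proteins shorter than the minimum
#' fragment length pass through unchanged. Deterministic under `seed`.
#'
#' @param records List of `protein_record`s.
#' @param config A [model_config()] (fields `enhance_prob`,
#'   `enhance_min_len`).
#' @param seed Integer seed.
#' @param enabled Set `FALSE` for the identity operation.
#' @return List of (possibly cropped) records.
#' @export
augment_batch <- function(records, config, seed = 1, enabled = TRUE) {
  if (!enabled || config$enhance_prob <= 0) return(records)
  run_seeded(seed, {
    lapply(records, function(r) {
      L <- nchar(r$sequence)
      if (L <= config$enhance_min_len) return(r)
      if (stats::runif(1) >= config$enhance_prob) return(r)
      len <- sample(config$enhance_min_len:L, 1)
      from <- sample(seq_len(L - len + 1L), 1)
      crop_record(r, from, from + len - 1L)
    })
  })
}
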