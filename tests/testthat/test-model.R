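# Model construction, forward-pass contracts, gradient correctness, batch
# behaviour and training-time fragment enhancement.

tiny_cfg <- function(tasks = c("IF", "BU", "S3", "SA"), ...) {
  model_config("tiny", active_tasks = tasks, dropout = 0, ...)
}

test_that("model construction creates one head per active task on a shared trunk", {
  m_single <- build_model(model_config("tiny", active_tasks = "IF"), seed = 1)
  expect_true("head_IF_W" %in% names(m_single$params))
  expect_false(any(grepl("head_(BU|S3|S8|SA)", names(m_single$params))))
  m_multi <- build_model(tiny_cfg(), seed = 1)
  expect_setequal(grep("^head_", names(m_multi$params), value = TRUE),
                  c("head_IF_W", "head_IF_b", "head_BU_W", "head_BU_b",
                    "head_S3_W", "head_S3_b", "head_SA_W", "head_SA_b"))
  # trunk parameters are the same set regardless of the head count
  trunk <- function(m) sort(grep("^head_", names(m$params), value = TRUE,
                                 invert = TRUE))
  expect_identical(trunk(m_single), trunk(m_multi))
  # tiny preset stays under 200k parameters
  expect_lt(n_parameters(build_model(model_config("tiny",
                                                  active_tasks = TASK_NAMES))),
            200000)
})

test_that("forward pass emits per-residue probabilities and is batch equivariant", {
  set.seed(41)
  lens <- c(50, 62, 71, 80)
  recs <- lapply(seq_along(lens), function(i)
    random_record(lens[i], id = paste0("B", i)))
  model <- build_model(tiny_cfg(), seed = 2)
  preds <- predict_mtppi(model, recs)
  expect_named(preds, c("IF", "BU", "S3", "SA"))
  for (i in seq_along(lens)) {
    expect_equal(dim(preds$IF[[i]]), c(lens[i], 2))
    expect_equal(dim(preds$S3[[i]]), c(lens[i], 3))
    expect_equal(rowSums(preds$S3[[i]]), rep(1, lens[i]), tolerance = 1e-9)
    expect_equal(rowSums(preds$IF[[i]]), rep(1, lens[i]), tolerance = 1e-9)
  }
  # permuting the batch permutes the outputs identically
  perm <- c(3, 1, 4, 2)
  preds_perm <- predict_mtppi(model, recs[perm])
  for (i in seq_along(perm))
    expect_equal(preds_perm$IF[[i]], preds$IF[[perm[i]]])
  # a protein's predictions do not depend on its batch companions
  solo <- predict_mtppi(model, recs[[2]])
  expect_equal(solo$IF[[1]], preds$IF[[2]], tolerance = 1e-12)
  bad <- random_record(10)
  bad$features <- bad$features[, 1:60]
  expect_error(predict_mtppi(model, list(bad)), "76")
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  cfg <- model_config("tiny", active_tasks = TASK_NAMES, d_model = 6L,
                      ff_dim = 8L, rnn_hidden = 4L, n_transformer = 1L,
                      n_cnn = 1L, n_birnn = 1L, dropout = 0, sa_scale = 0.01)
  model <- build_model(cfg, seed = 3)
  rec <- random_record(8)
  rec$masks$IF[3] <- FALSE; rec$labels$IF[3] <- NA
  w <- weight_scheme("A", TASK_NAMES, if_class_weight = 3)
  out <- model_loss_grad(model, list(rec), w)
  eps <- 1e-5
  worst <- 0
  for (nm in names(model$params)) {
    P <- model$params[[nm]]
    for (k in sample(length(P), min(2, length(P)))) {
      up <- model; up$params[[nm]][k] <- P[k] + eps
      dn <- model; dn$params[[nm]][k] <- P[k] - eps
      num <- (model_loss_grad(up, list(rec), w)$total -
                model_loss_grad(dn, list(rec), w)$total) / (2 * eps)
      ana <- if (!is.null(out$grads[[nm]])) out$grads[[nm]][k] else 0
      worst <- max(worst, abs(num - ana) / max(1e-6, abs(num), abs(ana)))
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("a fully masked task receives zero head gradients but shared-trunk coupling holds", {
  set.seed(43)
  rec <- random_record(20, if_mask = rep(FALSE, 20))
  rec$labels$IF <- rep(NA_real_, 20)
  model <- build_model(tiny_cfg(), seed = 4)
  w <- weight_scheme("A", c("IF", "BU", "S3", "SA"))
  out <- model_loss_grad(model, list(rec), w)
  # task-head isolation: no gradient reaches the masked task's head
  expect_true(is.null(out$grads$head_IF_W) ||
                all(out$grads$head_IF_W == 0))
  # related tasks still drive the shared trunk
  expect_gt(max(abs(out$grads$in_W)), 0)
  # multi-task trunk gradient differs from the single-task one
  m_single <- model
  m_single$config$tasks <- "IF"
  rec2 <- random_record(20)
  w_if <- loss_weights(IF = 1)
  g_single <- model_loss_grad(m_single, list(rec2), w_if)$grads$in_W
  model2 <- model
  g_multi <- model_loss_grad(model2, list(rec2), w)$grads$in_W
  expect_gt(max(abs(g_single - g_multi)), 0)
})

test_that("checkpoints round-trip config, parameters and predictions", {
  set.seed(45)
  model <- build_model(tiny_cfg(), seed = 9)
  rec <- random_record(12)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path, history = data.frame(epoch = 1, val = 0.7))
  back <- load_checkpoint(path)
  expect_equal(back$model$params, model$params)
  expect_equal(predict_mtppi(back$model, rec), predict_mtppi(model, rec))
  expect_equal(back$history$val, 0.7)
  saveRDS(list(a = 1), path)
  expect_error(load_checkpoint(path), "not an mtppi checkpoint")
})

test_that("fragment enhancement crops labels and masks consistently", {
  set.seed(44)
  cfg <- model_config("tiny", enhance_prob = 1, enhance_min_len = 10L)
  rec <- random_record(60)
  rec$labels$SA <- as.numeric(1:60)  # position markers
  rec$masks$SA <- rep(c(TRUE, FALSE), 30)
  out <- augment_batch(list(rec), cfg, seed = 6)[[1]]
  L2 <- nchar(out$sequence)
  expect_lte(L2, 60)
  expect_gte(L2, 10)
  from <- out$labels$SA[1]
  window <- from:(from + L2 - 1)
  expect_equal(out$labels$SA, as.numeric(window))
  expect_equal(out$masks$SA, rec$masks$SA[window])
  expect_equal(out$sequence, substr(rec$sequence, from, from + L2 - 1))
  expect_equal(out$features, rec$features[window, ])
  for (task in TASK_NAMES)
    expect_length(out$labels[[task]], L2)
  # disabled: identity
  expect_identical(augment_batch(list(rec), cfg, seed = 6, enabled = FALSE),
                   list(rec))
  # deterministic under seed
  expect_identical(augment_batch(list(rec), cfg, seed = 6),
                   augment_batch(list(rec), cfg, seed = 6))
  # proteins shorter than the minimum pass through unchanged
  short <- random_record(8)
  expect_identical(augment_batch(list(short), cfg, seed = 1)[[1]], short)
})
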