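# The masked multi-task loss: per-task losses, masking semantics, the
# composite combination, the class-imbalance weight, and the three
# weighting schemes.

test_that("per-task losses match closed forms", {
  # two residues predicted (0.5, 0.5): cross-entropy ln 2 per residue
  p <- matrix(0.5, 2, 2)
  expect_equal(task_loss(p, c(0, 1), c(TRUE, TRUE), "IF"), log(2))
  # all residues masked: zero
  expect_equal(task_loss(p, c(0, 1), c(FALSE, FALSE), "IF"), 0)
  # SA predictions equal to targets: zero MSE
  expect_equal(task_loss(c(10, 20, 30), c(10, 20, 30), rep(TRUE, 3), "SA"), 0)
  expect_error(task_loss(matrix(c(1.2, -0.2, 0.5, 0.5), 2, 2, byrow = TRUE),
                         c(0, 1), c(TRUE, TRUE), "BU"), "outside")
})

test_that("losses are exactly invariant to predictions at masked positions", {
  set.seed(31)
  for (rep in 1:5) {
    L <- 40
    rec <- random_record(L, if_mask = sample(c(TRUE, FALSE), L, replace = TRUE,
                                             prob = c(0.6, 0.4)))
    rec$masks$SA[sample(L, 10)] <- FALSE
    rec$labels$SA[!rec$masks$SA] <- NA
    rec$labels$IF[!rec$masks$IF] <- NA
    preds <- random_predictions(list(rec))
    w <- weight_scheme("A", TASK_NAMES, if_class_weight = 4)
    base <- multitask_loss(preds, list(rec), w)
    # perturb every masked position of every task
    pert <- preds
    for (task in TASK_NAMES) {
      m <- rec$masks[[task]]
      if (all(m)) next
      if (task == "SA") pert[[task]][[1]][!m] <- runif(sum(!m), 0, 500)
      else {
        K <- ncol(pert[[task]][[1]])
        pert[[task]][[1]][!m, ] <- random_probs(sum(!m), K)
      }
    }
    after <- multitask_loss(pert, list(rec), w)
    expect_identical(base$total, after$total)
    expect_identical(base$task_losses, after$task_losses)
  }
})

test_that("the total loss is the weighted sum of per-task losses", {
  set.seed(32)
  recs <- list(random_record(30), random_record(25))
  preds <- random_predictions(recs)
  w <- loss_weights(IF = 0.3, BU = 0.1, S3 = 0.2, S8 = 0.25, SA = 0.15,
                    if_class_weight = 2)
  rep <- multitask_loss(preds, recs, w)
  # independent recomputation of each pooled task loss
  manual <- 0
  for (task in TASK_NAMES) {
    num <- 0; cnt <- 0
    for (i in 1:2) {
      m <- recs[[i]]$masks[[task]]
      l <- loop_task_loss(preds[[task]][[i]], recs[[i]]$labels[[task]], m,
                          task, w$if_class_weight)
      num <- num + l * sum(m); cnt <- cnt + sum(m)
    }
    expect_equal(rep$task_losses[[task]], num / cnt, tolerance = 1e-10)
    manual <- manual + w$weights[[task]] * num / cnt
  }
  expect_equal(rep$total, manual, tolerance = 1e-12)
  # linearity: doubling every weight doubles the total
  w2 <- loss_weights(IF = 0.6, BU = 0.2, S3 = 0.4, S8 = 0.5, SA = 0.3,
                     if_class_weight = 2)
  expect_equal(multitask_loss(preds, recs, w2)$total, 2 * rep$total,
               tolerance = 1e-12)
  # single-task reduction
  w_if <- loss_weights(IF = 1, if_class_weight = 2)
  expect_equal(multitask_loss(preds, recs, w_if)$total,
               rep$task_losses$IF, tolerance = 1e-12)
})

test_that("a protein with a fully masked interface contributes only related-task losses", {
  set.seed(33)
  rec <- random_record(35, if_mask = rep(FALSE, 35))
  rec$labels$IF <- rep(NA_real_, 35)
  preds <- random_predictions(list(rec))
  w <- weight_scheme("A", TASK_NAMES)
  rep <- multitask_loss(preds, list(rec), w)
  expect_equal(rep$task_losses$IF, 0)
  expect_equal(rep$counts[["IF"]], 0)
  manual <- sum(vapply(c("BU", "S3", "S8", "SA"), function(t)
    w$weights[[t]] * rep$task_losses[[t]], numeric(1)))
  expect_equal(rep$total, manual, tolerance = 1e-12)
})

test_that("total_loss rejects weights on inactive tasks", {
  w <- loss_weights(IF = 0.5, SA = 0.5)
  expect_error(total_loss(list(IF = 1.0), w), "inactive")
  expect_equal(total_loss(list(IF = 1.0, SA = 2.0), w), 0.5 + 1.0)
})

test_that("the interface class weight scales exactly the positive terms", {
  set.seed(34)
  L <- 30
  p <- random_probs(L, 2)
  m <- rep(TRUE, L)
  # all-negative labels: weighted loss equals unweighted loss
  y0 <- rep(0, L)
  expect_identical(task_loss(p, y0, m, "IF", if_class_weight = 7),
                   task_loss(p, y0, m, "IF", if_class_weight = 1))
  # all-positive labels: loss scales by exactly w
  y1 <- rep(1, L)
  expect_equal(task_loss(p, y1, m, "IF", if_class_weight = 7),
               7 * task_loss(p, y1, m, "IF", if_class_weight = 1),
               tolerance = 1e-12)
  # mixed: decomposes into negative part + w * positive part
  y <- rbinom(L, 1, 0.4)
  l1 <- task_loss(p, y, m, "IF", if_class_weight = 1)
  lw <- task_loss(p, y, m, "IF", if_class_weight = 5)
  lpos <- sum(-log(p[cbind(which(y == 1), 2)])) / L
  expect_equal(lw, l1 + 4 * lpos, tolerance = 1e-12)
})

test_that("weighting schemes satisfy their defining constraints", {
  # Method A: equal weights, normalised
  wa <- weight_scheme("A", c("IF", "BU", "S3", "SA"))
  expect_equal(unname(wa$weights[c("IF", "BU", "S3", "SA")]), rep(0.25, 4))
  expect_equal(unname(wa$weights[["S8"]]), 0)
  # Method C with four tasks: interface holds half the total
  wc <- weight_scheme("C", c("IF", "BU", "S3", "SA"))
  expect_equal(wc$weights[["IF"]], 0.5)
  expect_equal(unname(wc$weights[c("BU", "S3", "SA")]), rep(1 / 6, 3))
  # Method C with all five: interface weight equals the sum of the others,
  # which are mutually equal
  wc5 <- weight_scheme("C", TASK_NAMES)
  expect_equal(wc5$weights[["IF"]],
               sum(wc5$weights[c("BU", "S3", "S8", "SA")]))
  expect_equal(length(unique(round(wc5$weights[c("BU", "S3", "S8", "SA")], 12))), 1)
  # Method B, similarity grouping {S3,S8} and {BU,SA}
  wb <- weight_scheme("B", TASK_NAMES, pairing = "similarity")
  expect_equal(wb$weights[["S3"]], wb$weights[["S8"]])
  expect_equal(wb$weights[["BU"]], wb$weights[["SA"]])
  expect_equal(wb$weights[["IF"]], wb$weights[["S3"]] + wb$weights[["S8"]])
  expect_equal(wb$weights[["IF"]], wb$weights[["BU"]] + wb$weights[["SA"]])
  # Method B, equation pairing {BU,S3} and {S8,SA}
  we <- weight_scheme("B", TASK_NAMES, pairing = "equation")
  expect_equal(we$weights[["BU"]], we$weights[["S3"]])
  expect_equal(we$weights[["S8"]], we$weights[["SA"]])
  expect_equal(we$weights[["IF"]], we$weights[["BU"]] + we$weights[["S3"]])
  expect_equal(we$weights[["IF"]], we$weights[["S8"]] + we$weights[["SA"]])
  # singleton group keeps full weight under the similarity grouping
  wsub <- weight_scheme("B", c("IF", "BU", "S3", "SA"), pairing = "similarity")
  expect_equal(wsub$weights[["S3"]], wsub$weights[["IF"]])
  expect_equal(wsub$weights[["BU"]] + wsub$weights[["SA"]], wsub$weights[["IF"]])
  # all schemes normalise to total weight 1 and require IF
  for (w in list(wa, wc, wc5, wb, we, wsub)) expect_equal(sum(w$weights), 1)
  expect_error(weight_scheme("A", c("BU", "SA")), "IF")
})

test_that("the training engine's loss agrees with the R reference", {
  set.seed(35)
  recs <- list(random_record(20), random_record(15, if_mask = rep(FALSE, 15)))
  recs[[2]]$labels$IF <- rep(NA_real_, 15)
  cfg <- model_config("tiny", active_tasks = TASK_NAMES, sa_scale = 1,
                      dropout = 0)
  model <- build_model(cfg, seed = 8)
  w <- weight_scheme("A", TASK_NAMES, if_class_weight = 3)
  engine <- model_loss_grad(model, recs, w)
  preds <- predict_mtppi(model, recs)
  reference <- multitask_loss(preds, recs, w)
  expect_equal(engine$total, reference$total, tolerance = 1e-8)
  for (task in TASK_NAMES)
    expect_equal(engine$task_losses[[task]], reference$task_losses[[task]],
                 tolerance = 1e-8)
})
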