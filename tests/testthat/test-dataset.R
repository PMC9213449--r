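# Dataset assembly: annotation matching, the dataset pair, seeded splits
# with the subset property, per-protein annotation masking, and the class
# imbalance weight.

make_records <- function(n, L = 20, n_annotated = n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    random_record(L, id = sprintf("P%03d_A", i),
                  if_mask = rep(i <= n_annotated, L)))
}

test_that("PPI annotations attach only on exact sequence agreement", {
  set.seed(21)
  recs <- lapply(1:3, function(i) {
    r <- random_record(10, id = paste0("1ab", i, "_A"),
                       if_mask = rep(FALSE, 10))
    r$labels$IF <- rep(NA_real_, 10)
    r
  })
  lab <- paste(rep("01", 5), collapse = "")
  tab <- data.frame(
    key = c("1ab1_A", "1ab2_A"),
    sequence = c(recs[[1]]$sequence, "WWWWWWWWWW"),
    labels = c(lab, lab), stringsAsFactors = FALSE)
  out <- match_ppi_annotations(recs, tab)
  expect_equal(out$report$status,
               c("matched", "sequence_mismatch", "no_annotation"))
  expect_true(all(out$records[[1]]$masks$IF))
  expect_equal(out$records[[1]]$labels$IF, rep(c(0L, 1L), 5))
  expect_true(all(!out$records[[2]]$masks$IF))
  expect_true(all(!out$records[[3]]$masks$IF))
  expect_error(match_ppi_annotations(recs, rbind(tab, tab[1, ])), "duplicate")
})

test_that("the dataset pair is a filtered subset relation", {
  recs <- make_records(10, n_annotated = 4)
  pair <- build_dataset_pair(recs)
  expect_length(pair$ppi, 4)
  expect_length(pair$extended, 10)
  ids_ppi <- vapply(pair$ppi, `[[`, "", "protein_id")
  ids_ext <- vapply(pair$extended, `[[`, "", "protein_id")
  expect_true(all(ids_ppi %in% ids_ext))
  none <- make_records(3, n_annotated = 0)
  expect_warning(pair0 <- build_dataset_pair(none), "empty")
  expect_length(pair0$ppi, 0)
})

test_that("splitting is 80/10/10, seeded, and preserves the pair subset property", {
  recs <- make_records(100, n_annotated = 40)
  sp <- split_dataset(recs, seed = 7)
  expect_equal(vapply(sp[c("train", "validation", "test")], length, 1L),
               c(train = 80L, validation = 10L, test = 10L))
  sp2 <- split_dataset(recs, seed = 7)
  expect_identical(sp$assignment, sp2$assignment)
  sp3 <- split_dataset(recs, seed = 8)
  expect_false(identical(sp$assignment, sp3$assignment))
  # pair: every PPI partition is a subset of the extended partition
  pair <- build_dataset_pair(recs)
  both <- split_dataset_pair(pair, seed = 3)
  for (part in c("train", "validation", "test")) {
    ids_ppi <- vapply(both$ppi[[part]], `[[`, "", "protein_id")
    ids_ext <- vapply(both$extended[[part]], `[[`, "", "protein_id")
    expect_true(all(ids_ppi %in% ids_ext))
  }
  expect_error(split_dataset(recs, fractions = c(0.8, 0.3, 0.1)), "sum to 1")
})

test_that("fractional masking is per protein, nested, and lossless", {
  recs <- make_records(80, n_annotated = 64)
  # identity at fraction 1
  m1 <- mask_ppi_fraction(recs, 1, seed = 5)
  expect_length(m1$kept_ids, 64)
  expect_identical(m1$records, recs)
  # 64 annotated at one eighth: exactly 8 keep labels
  m8 <- mask_ppi_fraction(recs, 1 / 8, seed = 5)
  expect_length(m8$kept_ids, 8)
  kept_masks <- vapply(m8$records, function(r) any(r$masks$IF), logical(1))
  expect_equal(sum(kept_masks), 8)
  # nesting under a fixed seed
  m2 <- mask_ppi_fraction(recs, 1 / 2, seed = 5)
  expect_true(all(m8$kept_ids %in% m2$kept_ids))
  # label values are never altered, only masks: unmasking is lossless
  for (i in seq_along(recs))
    expect_identical(m8$records[[i]]$labels, recs[[i]]$labels)
  expect_error(mask_ppi_fraction(recs, 0), "keep_fraction")
  expect_error(mask_ppi_fraction(recs, 1.2), "keep_fraction")
})

test_that("a masked protein contributes nothing to the interface loss", {
  recs <- make_records(6, L = 15, n_annotated = 6, seed = 9)
  masked <- mask_ppi_fraction(recs, 1 / 3, seed = 2)$records
  preds <- random_predictions(masked)
  w <- weight_scheme("A", TASK_NAMES)
  full_rep <- multitask_loss(preds, masked, w)
  # recompute using only the kept proteins' IF contributions
  kept <- vapply(masked, function(r) any(r$masks$IF), logical(1))
  rep_kept <- multitask_loss(lapply(preds, function(p) p[kept]),
                             masked[kept], w)
  expect_equal(full_rep$task_losses$IF, rep_kept$task_losses$IF,
               tolerance = 1e-12)
  expect_equal(full_rep$counts[["IF"]], rep_kept$counts[["IF"]])
})

test_that("the class weight is the observed non-interface / interface ratio", {
  # constructed toy realising the printed ratio: 637 negatives, 100 positives
  L <- 737
  rec <- random_record(L)
  rec$labels$IF <- c(rep(1, 100), rep(0, 637))
  rec$masks$IF <- rep(TRUE, L)
  expect_equal(compute_class_weight(list(rec)), 6.37)
  # balanced observed labels give exactly 1
  rec$labels$IF <- c(rep(0, 300), rep(1, 300), rep(0, 137))
  rec$masks$IF <- c(rep(TRUE, 600), rep(FALSE, 137))
  expect_equal(compute_class_weight(list(rec)), 1)
  # counting oracle on a synthetic set; invariant to protein order
  recs <- generate_dataset(synthetic_params(n_proteins = 20, seed = 3))
  w <- compute_class_weight(recs)
  n_pos <- n_neg <- 0
  for (r in recs) {
    m <- r$masks$IF
    n_pos <- n_pos + sum(r$labels$IF[m] == 1)
    n_neg <- n_neg + sum(r$labels$IF[m] == 0)
  }
  expect_equal(w, n_neg / n_pos)
  expect_equal(compute_class_weight(rev(recs)), w)
  # masked proteins are excluded from the counts
  masked <- mask_ppi_fraction(recs, 0.5, seed = 1)$records
  kept <- vapply(masked, function(r) any(r$masks$IF), logical(1))
  expect_equal(compute_class_weight(masked), compute_class_weight(masked[kept]))
  expect_error(compute_class_weight(list(random_record(5, if_mask = rep(FALSE, 5)))),
               "no observed interface")
})
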