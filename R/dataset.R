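# Dataset assembly: protein records (features + per-task labels + masks),
# matching of PPI annotations by PDB id/chain with exact sequence agreement,
# the PPI / extended dataset pair, seeded 80/10/10 splitting with a shared
# partition assignment, per-protein fractional masking of PPI annotations,
# and the interface class-imbalance weight.

#' Construct a protein record
#'
#' The unit of the dataset: one chain's sequence, its L x 76 feature matrix,
#' per-task label vectors and per-task observation masks (`TRUE` =
#' observed). All vectors must have length L; positions with `FALSE` mask
#' may carry `NA` labels.
#'
#' @param protein_id Identifier (conventionally PDB id + chain).
#' @param sequence Amino-acid sequence.
#' @param features L x 76 numeric matrix or a `feature_matrix`.
#' @param labels Named list: `IF`, `BU` 0/1; `S3` in 1..3; `S8` in 1..8;
#'   `SA` non-negative reals (angstrom^2). Missing tasks are filled with
#'   all-`NA` vectors.
#' @param masks Named list of logical vectors; missing tasks default to
#'   all-`FALSE` for tasks with all-`NA` labels and all-`TRUE` otherwise.
#' @return A `protein_record`.
#' @export
protein_record <- function(protein_id, sequence, features, labels,
                           masks = NULL) {
  if (inherits(features, "feature_matrix")) features <- features$values
  L <- nchar(sequence)
  stopifnot(is.matrix(features), nrow(features) == L, ncol(features) == 76)
  for (task in TASK_NAMES) {
    if (is.null(labels[[task]])) labels[[task]] <- rep(NA_real_, L)
    stopifnot(length(labels[[task]]) == L)
    if (is.null(masks[[task]]))
      masks[[task]] <- rep(!all(is.na(labels[[task]])), L)
    masks[[task]] <- as.logical(masks[[task]])
    stopifnot(length(masks[[task]]) == L)
    if (anyNA(labels[[task]][masks[[task]]]))
      stop("NA label at an observed (unmasked) position for task ", task)
  }
  structure(list(protein_id = protein_id, sequence = sequence,
                 features = unname(features),
                 labels = labels[TASK_NAMES], masks = masks[TASK_NAMES]),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  obs <- vapply(x$masks, sum, 1L)
  cat(sprintf("<protein_record> %s: %d residues; observed labels: %s\n",
              x$protein_id, nchar(x$sequence),
              paste(sprintf("%s %d", names(obs), obs), collapse = ", ")))
  invisible(x)
}

ppi_annotated <- function(record) any(record$masks$IF)

run_seeded <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Attach PPI interface annotations to feature records
#'
#' Annotations are matched by key (PDB id + chain). Interface labels are
#' attached only when the annotation-source sequence agrees exactly with the
#' record's sequence; on disagreement the annotation is discarded and the
#' record keeps a fully masked interface vector, mirroring how annotation
#' sets whose sequences no longer correspond to the structure set must be
#' dropped.
#'
#' @param records List of `protein_record`s (interface mask state will be
#'   overwritten).
#' @param ppi_table data.frame with columns `key` (matching `protein_id`),
#'   `sequence`, and `labels` (a string of 0/1 characters, one per residue).
#'   Duplicate keys are an error.
#' @return List with `records` (updated) and `report` (data.frame
#'   `protein_id`, `status` in matched/sequence_mismatch/no_annotation).
#' @export
match_ppi_annotations <- function(records, ppi_table) {
  if (anyDuplicated(ppi_table$key))
    stop("duplicate keys in PPI annotation table: ",
         paste(unique(ppi_table$key[duplicated(ppi_table$key)]), collapse = ", "))
  status <- character(length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    j <- match(rec$protein_id, ppi_table$key)
    L <- nchar(rec$sequence)
    if (is.na(j)) {
      status[i] <- "no_annotation"
    } else if (ppi_table$sequence[j] != rec$sequence) {
      status[i] <- "sequence_mismatch"
    } else {
      lab <- as.integer(strsplit(ppi_table$labels[j], "")[[1]])
      stopifnot(length(lab) == L, all(lab %in% 0:1))
      rec$labels$IF <- lab
      rec$masks$IF <- rep(TRUE, L)
      records[[i]] <- rec
      status[i] <- "matched"
      next
    }
    rec$labels$IF <- rep(NA_real_, L)
    rec$masks$IF <- rep(FALSE, L)
    records[[i]] <- rec
  }
  list(records = records,
       report = data.frame(protein_id = vapply(records, `[[`, "", "protein_id"),
                           status = status, stringsAsFactors = FALSE))
}

#' Build the PPI / extended dataset pair
#'
#' The PPI dataset holds every record with observed interface labels; the
#' extended dataset holds all records (structural labels for everything,
#' interface labels only where available), so the PPI dataset is a subset of
#' the extended one.
#'
#' @param all_records List of `protein_record`s.
#' @return List with `ppi` and `extended` record lists.
#' @export
build_dataset_pair <- function(all_records) {
  has_if <- vapply(all_records, ppi_annotated, logical(1))
  if (!any(has_if)) warning("no PPI-annotated records: the PPI dataset is empty")
  list(ppi = all_records[has_if], extended = all_records)
}

#' Split a dataset into train / validation / test partitions
#'
#' Random split by protein under a fixed seed. When `assignment` is given
#' (a named partition vector from a previous split), proteins present in it
#' reuse their partition, which keeps the PPI partitions strict subsets of
#' the extended-dataset partitions.
#'
#' @param records List of `protein_record`s.
#' @param fractions Train/validation/test fractions summing to 1 (default
#'   0.8/0.1/0.1 by protein count, plus/minus rounding).
#' @param seed Integer seed.
#' @param assignment Optional named character vector protein_id ->
#'   `"train"`/`"validation"`/`"test"` to reuse.
#' @return A `dataset_split`: list with `train`, `validation`, `test` record
#'   lists and `assignment`.
#' @export
split_dataset <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1,
                          assignment = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("split fractions must sum to 1")
  ids <- vapply(records, `[[`, "", "protein_id")
  part <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(assignment)) {
    reuse <- ids %in% names(assignment)
    part[reuse] <- assignment[ids[reuse]]
  }
  todo <- which(is.na(part))
  n <- length(ids)
  n_test <- round(n * fractions[3]); n_val <- round(n * fractions[2])
  # fill remaining quota after reused assignments
  quota <- c(train = n - n_val - n_test, validation = n_val, test = n_test) -
    table(factor(part, levels = c("train", "validation", "test")))
  quota <- pmax(quota, 0)
  pool <- run_seeded(seed, sample(todo))
  lab <- rep(c("train", "validation", "test"), times = quota)
  if (length(lab) < length(pool))
    lab <- c(lab, rep("train", length(pool) - length(lab)))
  part[pool] <- lab[seq_along(pool)]
  structure(list(train = records[part == "train"],
                 validation = records[part == "validation"],
                 test = records[part == "test"],
                 assignment = part),
            class = "dataset_split")
}

#' Split the PPI / extended pair with a shared assignment
#'
#' Splits the extended dataset, then derives the PPI split by reusing each
#' PPI-annotated protein's partition, so each PPI partition is a strict
#' subset of the matching extended partition.
#'
#' @param pair List from [build_dataset_pair()].
#' @param fractions,seed See [split_dataset()].
#' @return List with `ppi` and `extended` `dataset_split`s.
#' @export
split_dataset_pair <- function(pair, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  ext <- split_dataset(pair$extended, fractions, seed)
  ppi <- split_dataset(pair$ppi, fractions, seed, assignment = ext$assignment)
  list(ppi = ppi, extended = ext)
}

#' Mask the interface annotation of a random fraction of proteins
#'
#' Keeps interface labels for a random `keep_fraction` of the PPI-annotated
#' *proteins* and masks the entire interface vector of every other annotated
#' protein (the masking is always per protein, never per residue; label
#' values are retained so the operation is lossless under re-masking).
#' Structural labels are untouched. The kept sets are nested across
#' fractions for a fixed seed: the kept set at a smaller fraction is a
#' subset of the kept set at a larger one.
#'
#' @param records List of `protein_record`s.
#' @param keep_fraction Fraction in (0, 1] of annotated proteins keeping
#'   their interface labels.
#' @param seed Integer seed (the kept set depends on the seed only, not on
#'   the fraction, which yields the nesting).
#' @return List with `records` (masked) and `kept_ids` (protein ids that
#'   keep interface labels).
#' @export
mask_ppi_fraction <- function(records, keep_fraction, seed = 1) {
  if (!(keep_fraction > 0 && keep_fraction <= 1))
    stop("keep_fraction must be in (0, 1]")
  ann <- which(vapply(records, ppi_annotated, logical(1)))
  perm <- run_seeded(seed, sample(ann))
  n_keep <- max(1L, round(length(ann) * keep_fraction))
  if (keep_fraction == 1) n_keep <- length(ann)
  kept <- perm[seq_len(n_keep)]
  drop <- setdiff(ann, kept)
  for (i in drop)
    records[[i]]$masks$IF <- rep(FALSE, nchar(records[[i]]$sequence))
  list(records = records,
       kept_ids = vapply(records[kept], `[[`, "", "protein_id"))
}

#' Interface class-imbalance weight
#'
#' The ratio of observed non-interface residues to observed interface
#' residues, counted over the supplied records' unmasked interface positions
#' (conventionally training plus validation). Used as the positive-class
#' weight in the interface cross-entropy.
#'
#' @param records List of `protein_record`s.
#' @return Positive real weight.
#' @export
compute_class_weight <- function(records) {
  n_pos <- n_neg <- 0
  for (rec in records) {
    m <- rec$masks$IF
    if (!any(m)) next
    y <- rec$labels$IF[m]
    n_pos <- n_pos + sum(y == 1)
    n_neg <- n_neg + sum(y == 0)
  }
  if (n_pos == 0) stop("no observed interface residues: class weight undefined")
  n_neg / n_pos
}
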