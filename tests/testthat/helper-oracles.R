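# Independent reference implementations used to validate the package's
# (possibly accelerated or vectorised) routines.

TASK_NAMES <- c("IF", "BU", "S3", "S8", "SA")

vdw_radius <- function(elements, radii = vdw_radius_table()) {
  unname(radii[toupper(elements)])
}

# O(A^2) all-pairs interface labeling over a parsed structure_model
brute_force_interface <- function(structure, pad = 0.5,
                                  radii = vdw_radius_table()) {
  chains <- structure$chains
  labels <- lapply(chains, function(ch) integer(nrow(ch$residues)))
  nc <- length(chains)
  for (ci in seq_len(nc - 1)) for (cj in (ci + 1):nc) {
    a <- chains[[ci]]$atoms; b <- chains[[cj]]$atoms
    ra <- vdw_radius(a$element, radii); rb <- vdw_radius(b$element, radii)
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
      if (d < ra[i] + rb[j] + pad) {
        labels[[ci]][match(a$resno[i], chains[[ci]]$residues$resno)] <- 1L
        labels[[cj]][match(b$resno[j], chains[[cj]]$residues$resno)] <- 1L
      }
    }
  }
  labels
}

# pairwise-count AUC ROC oracle: P(score_pos > score_neg) + 0.5 P(tie)
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# rank/threshold enumeration oracle for average precision
enumeration_ap <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; ap <- 0
  for (th in thresholds) {
    called <- scores >= th
    prec <- sum(labels[called] == 1) / sum(called)
    rec <- sum(labels[called] == 1) / n_pos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# per-residue scalar-loop loss oracle (no vectorisation)
loop_task_loss <- function(predictions, targets, mask, task,
                           if_class_weight = 1) {
  total <- 0; n <- 0
  for (i in seq_along(mask)) {
    if (!mask[i]) next
    n <- n + 1
    if (task == "SA") {
      total <- total + (predictions[i] - targets[i])^2
    } else {
      cls <- if (task %in% c("IF", "BU")) targets[i] + 1 else targets[i]
      ce <- -log(predictions[i, cls])
      if (task == "IF" && cls == 2) ce <- ce * if_class_weight
      total <- total + ce
    }
  }
  if (n == 0) 0 else total / n
}

# random probability matrix with rows summing to 1
random_probs <- function(L, K) {
  m <- matrix(stats::runif(L * K, 0.05, 1), L, K)
  m / rowSums(m)
}

# a random fully populated protein record for loss/model tests
random_record <- function(L, id = "R1", if_mask = rep(TRUE, L),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- sample(sort(unname(amino_acids())), L, replace = TRUE)
  protein_record(
    id, paste(aa, collapse = ""),
    matrix(stats::rnorm(L * 76), L, 76),
    labels = list(IF = ifelse(if_mask, stats::rbinom(L, 1, 0.2), NA),
                  BU = stats::rbinom(L, 1, 0.4),
                  S3 = sample(3, L, replace = TRUE),
                  S8 = sample(8, L, replace = TRUE),
                  SA = stats::runif(L, 0, 250)),
    masks = list(IF = if_mask, BU = rep(TRUE, L), S3 = rep(TRUE, L),
                 S8 = rep(TRUE, L), SA = rep(TRUE, L)))
}

# random per-task prediction set matching a list of records
random_predictions <- function(records, tasks = c("IF", "BU", "S3", "S8", "SA")) {
  out <- list()
  for (task in tasks) {
    out[[task]] <- lapply(records, function(r) {
      L <- nchar(r$sequence)
      if (task == "SA") matrix(stats::runif(L, 0, 250), L, 1)
      else random_probs(L, c(IF = 2, BU = 2, S3 = 3, S8 = 8)[[task]])
    })
  }
  out
}
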