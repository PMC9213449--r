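# Per-residue input feature encoding: a protein of length L is represented by
# an L x 76 matrix laid out as 20 PSSM log-odds columns, 30 HMM profile
# columns, 7 physicochemical property columns and 19 rigid-block indicator
# columns.

#' Feature block layout
#'
#' Column ranges of the four feature blocks within the 76-column feature
#' matrix (1-based, inclusive).
#'
#' @return Named list of integer vectors `pssm`, `hmm`, `phys7`, `psp19`.
#' @export
feature_blocks <- function() {
  list(pssm = 1:20, hmm = 21:50, phys7 = 51:57, psp19 = 58:76)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the 20 position-specific log-odds columns of a PSSM produced with
#' PSI-BLAST's `-out_ascii_pssm` option and checks the file's residue column
#' against the expected sequence.
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence Expected amino-acid sequence (single string). The file's
#'   residue column must match it exactly.
#' @param normalize `"none"` (default) keeps raw log-odds; `"sigmoid"` maps
#'   each value through 1 / (1 + exp(-x)).
#' @return Numeric matrix, length(sequence) x 20, columns in the file's
#'   amino-acid order.
#' @export
parse_pssm <- function(path, sequence, normalize = c("none", "sigmoid")) {
  normalize <- match.arg(normalize)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*A\\s+R\\s+N\\s+D", lines)
  if (length(hdr) == 0L)
    stop("not a PSI-BLAST ASCII PSSM: amino-acid header row not found in ", path)
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  body <- body[grepl("^\\s*[0-9]+\\s+[A-Za-z]\\s", body)]
  if (length(body) == 0L) stop("truncated PSSM file: no residue rows in ", path)
  toks <- strsplit(trimws(body), "\\s+")
  aa <- vapply(toks, `[[`, "", 2L)
  seq_chars <- strsplit(sequence, "")[[1]]
  if (length(aa) != length(seq_chars) || !all(aa == seq_chars))
    stop("PSSM residue column does not match the provided sequence")
  scores <- t(vapply(toks, function(tk) {
    if (length(tk) < 22L) stop("truncated PSSM row: fewer than 20 score columns")
    as.numeric(tk[3:22])
  }, numeric(20)))
  if (any(!is.finite(scores))) stop("non-numeric value in PSSM score columns")
  if (normalize == "sigmoid") scores <- 1 / (1 + exp(-scores))
  unname(scores)
}

# Integer HHM scores are stored as -1000*log2(p); '*' encodes probability 0.
hhm_score_to_prob <- function(tokens) {
  ifelse(tokens == "*", 0, 2^(-as.numeric(ifelse(tokens == "*", "0", tokens)) / 1000))
}

#' Parse an HHblits HHM profile file
#'
#' Reads the per-residue profile of an HHblits `.hhm` file: 20 match-state
#' emission values followed by 7 transition frequencies and 3 local diversity
#' (Neff) values, 30 columns in total. Integer scores x are converted to
#' 2^(-x/1000); the `*` token (zero probability) maps to 0, so every value
#' lies in [0, 1].
#'
#' @param path Path to the HHM file.
#' @param sequence Expected amino-acid sequence; the residue letters of the
#'   match-state lines must agree.
#' @return Numeric matrix, length(sequence) x 30.
#' @export
parse_hhm <- function(path, sequence) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^HMM\\b", lines)
  if (length(start) == 0L) stop("missing HMM block delimiter in ", path)
  i <- start[1] + 3L  # skip 'HMM' header, transition header, begin-state row
  aa <- character(0)
  rows <- list()
  while (i <= length(lines) && !startsWith(lines[i], "//")) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    res_tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    # layout: residue letter, position, 20 emission scores, trailing position
    if (length(res_tok) < 22L) stop("malformed HHM match-emission line: ", lines[i])
    if (i + 1L > length(lines)) stop("truncated HHM file: missing transition line")
    tr_tok <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(tr_tok) < 10L) stop("malformed HHM transition line: ", lines[i + 1L])
    aa <- c(aa, res_tok[1])
    rows[[length(rows) + 1L]] <-
      c(hhm_score_to_prob(res_tok[3:22]), hhm_score_to_prob(tr_tok[1:10]))
    i <- i + 2L
  }
  seq_chars <- strsplit(sequence, "")[[1]]
  if (length(aa) != length(seq_chars) || !all(aa == seq_chars))
    stop("HHM residue column does not match the provided sequence")
  m <- do.call(rbind, rows)
  unname(m)
}

phys7_fallback_row <- function() colMeans(meiler_table())

#' Physicochemical property features
#'
#' Seven amino-acid property scales (steric parameter, polarizability,
#' volume, hydrophobicity, isoelectric point, helix and sheet propensity) per
#' residue. Protein independent: the row depends only on the residue identity.
#' Unknown residues (e.g. `X`) receive the mean of the 20 canonical rows.
#'
#' @param sequence Amino-acid sequence (single string).
#' @return Numeric matrix, nchar(sequence) x 7.
#' @export
physchem_features <- function(sequence) {
  tab <- meiler_table()
  chars <- strsplit(toupper(sequence), "")[[1]]
  out <- matrix(NA_real_, length(chars), 7)
  known <- chars %in% rownames(tab)
  out[known, ] <- tab[chars[known], , drop = FALSE]
  if (any(!known))
    out[!known, ] <- matrix(phys7_fallback_row(), sum(!known), 7, byrow = TRUE)
  unname(out)
}

#' Rigid-block (PSP) indicator features
#'
#' Binary indicators for the presence of each of 19 side-chain/backbone
#' rigid-body blocks in a residue type; a residue may contain several blocks.
#' Protein independent. Unknown residues receive an all-zero row.
#'
#' @param sequence Amino-acid sequence (single string).
#' @return Integer 0/1 matrix, nchar(sequence) x 19.
#' @export
psp19_features <- function(sequence) {
  tab <- psp19_table()
  chars <- strsplit(toupper(sequence), "")[[1]]
  out <- matrix(0L, length(chars), 19)
  known <- chars %in% rownames(tab)
  out[known, ] <- tab[chars[known], , drop = FALSE]
  unname(out)
}

#' Assemble the 76-column feature matrix for one protein
#'
#' Concatenates, in fixed order, the 20 PSSM columns, 30 HMM columns, 7
#' physicochemical columns and 19 rigid-block columns.
#'
#' @param sequence Amino-acid sequence (single string).
#' @param pssm Either a path to a PSI-BLAST ASCII PSSM file or an L x 20
#'   numeric matrix.
#' @param hhm Either a path to an HHblits HHM file or an L x 30 numeric
#'   matrix.
#' @param protein_id Identifier stored in the result.
#' @param pssm_normalize Passed to [parse_pssm()] when `pssm` is a path.
#' @return A `feature_matrix` object: list with `protein_id`, `length`,
#'   `values` (L x 76 matrix) and `column_blocks` (see [feature_blocks()]).
#' @export
encode_protein <- function(sequence, pssm, hhm, protein_id = "protein",
                           pssm_normalize = "none") {
  L <- nchar(sequence)
  if (is.character(pssm)) pssm <- parse_pssm(pssm, sequence, pssm_normalize)
  if (is.character(hhm)) hhm <- parse_hhm(hhm, sequence)
  stopifnot(is.matrix(pssm), nrow(pssm) == L, ncol(pssm) == 20,
            is.matrix(hhm), nrow(hhm) == L, ncol(hhm) == 30)
  values <- cbind(pssm, hhm, physchem_features(sequence),
                  psp19_features(sequence))
  if (any(!is.finite(values))) stop("non-finite value in feature matrix")
  structure(list(protein_id = protein_id, length = L, values = unname(values),
                 column_blocks = feature_blocks()),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d residues x %d features (PSSM 20 | HMM 30 | PHYS 7 | PSP 19)\n",
              x$protein_id, x$length, ncol(x$values)))
  invisible(x)
}
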