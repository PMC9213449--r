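# Structure-derived gold-standard labels: interface residues from inter-chain
# atomic contacts, buried residues from relative solvent accessibility, and
# secondary structure / accessibility from DSSP output files.

standard_resid3 <- function() names(amino_acids())

#' Parse a multi-chain protein structure
#'
#' Reads a PDB or mmCIF coordinate file (via bio3d), keeps protein chains
#' only (standard amino acids; waters and other heteroatoms excluded),
#' resolves alternate locations to the highest-occupancy conformer, and
#' returns an ordered chain/residue/atom model.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (default, by file extension), `"pdb"` or `"cif"`.
#' @return A `structure_model`: list with `structure_id` and `chains`, each
#'   chain a list with `chain_id`, `residues` (data.frame: `resno`, `resid`,
#'   `aa`, `n_atoms`) and `atoms` (data.frame: `resno`, `name`, `element`,
#'   `x`, `y`, `z`).
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file does not exist: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  obj <- suppressWarnings(
    if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
  at <- obj$atom
  aa3 <- amino_acids()
  keep <- at$type == "ATOM" & at$resid %in% names(aa3)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no protein chains with standard residues in ", path)
  # resolve altLocs: within each (chain, resno, insert, atom name) keep the
  # highest-occupancy record; ties resolve to the first (altLoc order)
  occ <- at$o
  occ[is.na(occ)] <- 1
  grp <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(grp, -occ, seq_len(nrow(at)))
  at <- at[ord[!duplicated(grp[ord])], , drop = FALSE]
  at <- at[order(match(at$chain, unique(at$chain)), at$resno), , drop = FALSE]
  elem <- at$elesy
  miss <- is.na(elem) | !nzchar(trimws(elem))
  if (any(miss)) elem[miss] <- substr(gsub("[0-9]", "", trimws(at$elety[miss])), 1, 1)
  elem <- toupper(trimws(elem))
  chains <- lapply(unique(at$chain), function(ch) {
    sub <- at[at$chain == ch, , drop = FALSE]
    ures <- !duplicated(sub$resno)
    resdf <- data.frame(resno = sub$resno[ures], resid = sub$resid[ures],
                        aa = unname(aa3[sub$resid[ures]]),
                        n_atoms = as.integer(table(factor(sub$resno, levels = sub$resno[ures]))),
                        stringsAsFactors = FALSE)
    list(chain_id = ch, residues = resdf,
         atoms = data.frame(resno = sub$resno, name = trimws(sub$elety),
                            element = elem[at$chain == ch],
                            x = sub$x, y = sub$y, z = sub$z,
                            stringsAsFactors = FALSE))
  })
  names(chains) <- unique(at$chain)
  structure(list(structure_id = sub("\\.(pdb|cif)$", "", basename(path),
                                    ignore.case = TRUE),
                 chains = chains),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d chain(s): %s\n", x$structure_id,
              length(x$chains),
              paste(sprintf("%s (%d res)", names(x$chains),
                            vapply(x$chains, function(c) nrow(c$residues), 1L)),
                    collapse = ", ")))
  invisible(x)
}

# flat atom table across chains with per-chain residue positions
flatten_atoms <- function(structure) {
  do.call(rbind, lapply(seq_along(structure$chains), function(ci) {
    ch <- structure$chains[[ci]]
    data.frame(chain = ci,
               res = match(ch$atoms$resno, ch$residues$resno),
               element = ch$atoms$element,
               x = ch$atoms$x, y = ch$atoms$y, z = ch$atoms$z,
               stringsAsFactors = FALSE)
  }))
}

#' Interface residue labels from inter-chain atomic contacts
#'
#' A residue is an interface residue when any of its atoms lies within
#' contact distance of an atom in a residue of a *different* chain; the
#' contact threshold for an atom pair is the sum of their van der Waals radii
#' plus `pad` (default 0.5 angstrom). Labeling is symmetric: both partner
#' residues are labeled. Uses a cell-list spatial hash (cell size
#' 2 * max(radius) + pad) so the expected cost is linear in atom count.
#'
#' @param structure A `structure_model` with at least two chains.
#' @param pad Distance pad in angstrom added to the radius sum.
#' @param radii Named element -> radius table, see [vdw_radius_table()].
#' @return Named list, one 0/1 integer vector per chain (aligned with the
#'   chain's residue order). For a single-chain structure every label is `NA`
#'   (interface undefined) and a warning is raised.
#' @export
compute_interface_labels <- function(structure, pad = 0.5,
                                     radii = vdw_radius_table()) {
  nres <- vapply(structure$chains, function(c) nrow(c$residues), 1L)
  if (length(structure$chains) < 2L) {
    warning("interface labels undefined for a single-chain structure; returning NA")
    return(lapply(stats::setNames(nres, names(structure$chains)),
                  function(n) rep(NA_integer_, n)))
  }
  at <- flatten_atoms(structure)
  r <- vdw_radius(at$element, radii)
  labels <- lapply(nres, function(n) integer(n))
  cs <- 2 * max(r) + pad
  cell <- cbind(floor(at$x / cs), floor(at$y / cs), floor(at$z / cs))
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  idx_by_cell <- split(seq_len(nrow(at)), key)
  cell_of <- unique(cbind(cell, match(key, names(idx_by_cell))))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  for (k in seq_len(nrow(cell_of))) {
    A <- idx_by_cell[[cell_of[k, 4]]]
    nb_keys <- paste(cell_of[k, 1] + offs[, 1], cell_of[k, 2] + offs[, 2],
                     cell_of[k, 3] + offs[, 3])
    B <- unlist(idx_by_cell[intersect(nb_keys, names(idx_by_cell))],
                use.names = FALSE)
    for (i in A) {
      cand <- B[at$chain[B] != at$chain[i]]
      if (length(cand) == 0L) next
      d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
        (xyz[cand, 3] - xyz[i, 3])^2
      hit <- cand[d2 < (r[i] + r[cand] + pad)^2]
      if (length(hit)) {
        labels[[at$chain[i]]][at$res[i]] <- 1L
        for (j in hit) labels[[at$chain[j]]][at$res[j]] <- 1L
      }
    }
  }
  stats::setNames(labels, names(structure$chains))
}

#' Parse a DSSP output file
#'
#' Reads the per-residue records of a classic DSSP output file: chain,
#' author residue number, amino acid, eight-state secondary structure code
#' and absolute solvent accessibility (ACC, angstrom^2). Chain-break markers
#' (`!`) emit no residue; a blank structure code is coil (`C`); lower-case
#' amino-acid letters (SS-bonded cysteines) are read as `C`ys.
#'
#' @param path Path to a `.dssp` file.
#' @return data.frame with columns `chain`, `resno`, `aa`, `s8` (one of
#'   C,S,T,H,G,I,E,B) and `asa`.
#' @export
parse_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) stop("malformed DSSP file: residue header not found in ", path)
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  body <- body[nzchar(body)]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]; aa <- aa[keep]
  aa[aa %in% letters] <- "C"
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "C"
  bad <- !ss %in% s8_classes()
  if (any(bad)) stop("unknown DSSP structure code(s): ",
                     paste(unique(ss[bad]), collapse = ", "))
  data.frame(chain = substr(body, 12, 12),
             resno = as.integer(substr(body, 6, 10)),
             aa = aa, s8 = ss,
             asa = as.numeric(substr(body, 35, 38)),
             stringsAsFactors = FALSE)
}

#' Secondary-structure class sets
#'
#' `s8_classes()` returns the eight DSSP codes in the package's canonical
#' order: C (coil), S (high-curvature bend), T (turn), H (alpha-helix),
#' G (3-10 helix), I (pi-helix), E (strand), B (bridge). `s3_classes()`
#' returns the three-state codes C (coil), H (helix), E (strand).
#'
#' @return Character vector of class codes.
#' @export
s8_classes <- function() c("C", "S", "T", "H", "G", "I", "E", "B")

#' @rdname s8_classes
#' @export
s3_classes <- function() c("C", "H", "E")

#' Collapse eight-state secondary structure to three states
#'
#' Coil, high-curvature bend and turn collapse to coil; alpha-, 3-10- and
#' pi-helix to helix; strand and bridge to strand. The mapping is a partition
#' of the eight classes.
#'
#' @param s8 Character vector of DSSP codes (see [s8_classes()]).
#' @return Character vector over [s3_classes()].
#' @export
map_s8_to_s3 <- function(s8) {
  map <- c(C = "C", S = "C", T = "C", H = "H", G = "H", I = "H",
           E = "E", B = "E")
  out <- map[s8]
  if (anyNA(out)) stop("unknown S8 class token(s): ",
                       paste(unique(s8[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Buried-residue label from absolute solvent accessibility
#'
#' A residue is buried when its absolute solvent accessibility is less than
#' 7 percent of the residue type's maximum accessibility (strict `<`).
#'
#' @param asa Absolute solvent accessibility, angstrom^2 (vectorised).
#' @param residue_name One-letter residue code(s), recycled against `asa`.
#' @param threshold Relative-accessibility threshold (default 0.07).
#' @return Integer 0/1 vector; `NA` propagates from `asa`.
#' @export
compute_buried_label <- function(asa, residue_name, threshold = 0.07) {
  max_asa <- max_asa_table()[toupper(residue_name)]
  if (anyNA(max_asa)) stop("unknown residue name(s): ",
                           paste(unique(residue_name[is.na(max_asa)]), collapse = ", "))
  as.integer(asa / max_asa < threshold)
}

#' Shrake-Rupley accessible surface area
#'
#' Numerical accessible-surface-area computation over the structure's heavy
#' atoms: each atom is sampled with `n_points` sphere points at radius
#' vdW + probe; points not occluded by any neighbouring atom sphere
#' contribute to the atom's exposed area. Per-residue ASA is the sum over the
#' residue's atoms. Intended for desk-scale fixtures where no DSSP output is
#' available.
#'
#' @param structure A `structure_model`.
#' @param n_points Sphere sample points per atom (default 92).
#' @param probe Probe radius in angstrom (default 1.4, water).
#' @param radii Element radius table.
#' @return data.frame with `chain`, `resno`, `asa`.
#' @export
shrake_rupley_asa <- function(structure, n_points = 92, probe = 1.4,
                              radii = vdw_radius_table()) {
  at <- flatten_atoms(structure)
  r <- vdw_radius(at$element, radii) + probe
  xyz <- as.matrix(at[, c("x", "y", "z")])
  # deterministic golden-spiral sphere points
  k <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * k / n_points)
  theta <- pi * (1 + sqrt(5)) * k
  sph <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  n <- nrow(at)
  atom_asa <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums((xyz - matrix(xyz[i, ], n, 3, byrow = TRUE))^2)
    nb <- which(d2 < (r[i] + r)^2 & seq_len(n) != i)
    pts <- sph * r[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dd <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      exposed <- exposed & dd > r[j]^2
      if (!any(exposed)) break
    }
    atom_asa[i] <- 4 * pi * r[i]^2 * sum(exposed) / n_points
  }
  agg <- stats::aggregate(atom_asa,
                          by = list(chain = at$chain, resno = at$res), FUN = sum)
  data.frame(chain = names(structure$chains)[agg$chain],
             resno = vapply(seq_len(nrow(agg)), function(i)
               structure$chains[[agg$chain[i]]]$residues$resno[agg$resno[i]], 1),
             asa = agg$x, stringsAsFactors = FALSE)
}

#' Per-residue annotations and observation masks for a structure
#'
#' Combines interface labels (inter-chain contacts), DSSP-derived secondary
#' structure and solvent accessibility, and the buried rule into one
#' annotation table per chain, together with per-task observation masks:
#' residues with incomplete side chains (fewer heavy atoms than the canonical
#' count for the residue type) are masked for SA and BU; when
#' `ppi_available = FALSE`, or the structure has a single chain, the whole
#' interface vector is masked; residues without a DSSP record are masked for
#' S3/S8/SA/BU. Masked residues are excluded from loss and metrics
#' downstream.
#'
#' @param structure A `structure_model`.
#' @param dssp data.frame from [parse_dssp()] covering the structure's
#'   chains, or `NULL` to compute SA internally via [shrake_rupley_asa()]
#'   (secondary structure then stays unobserved).
#' @param ppi_available Logical: does this structure carry PPI interface
#'   annotation?
#' @param pad,radii Contact parameters, see [compute_interface_labels()].
#' @return data.frame with columns `chain_id`, `residue_index` (0-based
#'   within chain), `resno`, `residue_name`, `IF`, `BU`, `S3`, `S8`, `SA`,
#'   `mask_IF`, `mask_BU`, `mask_S3`, `mask_S8`, `mask_SA`.
#' @export
build_annotations <- function(structure, dssp = NULL, ppi_available = TRUE,
                              pad = 0.5, radii = vdw_radius_table()) {
  multi <- length(structure$chains) >= 2L
  if_labels <- if (multi) compute_interface_labels(structure, pad, radii) else NULL
  if (is.null(dssp)) {
    sr <- shrake_rupley_asa(structure, radii = radii)
    dssp <- data.frame(chain = sr$chain, resno = sr$resno, aa = NA_character_,
                       s8 = NA_character_, asa = sr$asa, stringsAsFactors = FALSE)
  }
  out <- lapply(seq_along(structure$chains), function(ci) {
    ch <- structure$chains[[ci]]
    n <- nrow(ch$residues)
    drows <- dssp[dssp$chain == ch$chain_id, , drop = FALSE]
    if (nrow(drows) > n)
      stop("DSSP records exceed structure residues for chain ", ch$chain_id)
    m <- match(ch$residues$resno, drows$resno)
    mism <- !is.na(m) & !is.na(drows$aa[m]) & drows$aa[m] != ch$residues$aa
    if (any(mism))
      stop("DSSP residue identity mismatch for chain ", ch$chain_id,
           " at resno ", paste(ch$residues$resno[which(mism)], collapse = ", "))
    s8 <- drows$s8[m]
    asa <- drows$asa[m]
    bu <- ifelse(is.na(asa), NA_integer_,
                 compute_buried_label(ifelse(is.na(asa), 0, asa), ch$residues$aa))
    incomplete <- ch$residues$n_atoms < heavy_atom_counts()[ch$residues$aa]
    mask_sa <- !is.na(asa) & !incomplete
    ifv <- if (multi) if_labels[[ci]] else rep(NA_integer_, n)
    mask_if <- rep(isTRUE(ppi_available) && multi, n)
    if (!all(mask_if)) ifv <- rep(NA_integer_, n)
    data.frame(chain_id = ch$chain_id, residue_index = seq_len(n) - 1L,
               resno = ch$residues$resno, residue_name = ch$residues$aa,
               IF = ifv, BU = ifelse(mask_sa, bu, NA_integer_),
               S3 = ifelse(is.na(s8), NA_character_, map_s8_to_s3(ifelse(is.na(s8), "C", s8))),
               S8 = s8, SA = ifelse(mask_sa, asa, NA_real_),
               mask_IF = mask_if, mask_BU = mask_sa,
               mask_S3 = !is.na(s8), mask_S8 = !is.na(s8), mask_SA = mask_sa,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write an annotation table as TSV
#'
#' Missing values are written as `"."`.
#'
#' @param annotations data.frame from [build_annotations()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_annotations_tsv <- function(annotations, path) {
  out <- annotations
  for (cl in names(out)) {
    v <- out[[cl]]
    if (is.logical(v)) v <- as.integer(v)
    v <- as.character(v)
    v[is.na(v)] <- "."
    out[[cl]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
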