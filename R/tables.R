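# Embedded reference tables: amino-acid constants used for label generation
# and feature encoding. All tables are keyed by one- or three-letter residue
# codes; lookups of unknown keys are explicit errors unless a documented
# fallback exists.

#' Standard amino acids
#'
#' One- and three-letter codes for the 20 standard amino acids, in the
#' conventional alphabetical one-letter order used throughout the package.
#'
#' @return Named character vector mapping three-letter codes (upper case) to
#'   one-letter codes.
#' @export
amino_acids <- function() {
  c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
    GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
    LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
    SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
}

#' Van der Waals radius table
#'
#' Element-keyed van der Waals radii (angstrom) used by the interface contact
#' criterion: two atoms are in contact when their distance is below the sum of
#' their radii plus a pad (default 0.5 angstrom). The default table covers the
#' elements found in protein heavy-atom models plus hydrogen and selenium
#' (selenomethionine). Lookup of an element absent from the table is an error,
#' never a silent default.
#'
#' @param overrides Optional named numeric vector of element -> radius
#'   replacing or extending the defaults.
#' @return Named numeric vector, element symbol (upper case) -> radius in
#'   angstrom.
#' @export
vdw_radius_table <- function(overrides = NULL) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           SE = 1.90, H = 1.20)
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("radius overrides must be a named numeric vector")
    if (any(!is.finite(overrides)) || any(overrides <= 0))
      stop("van der Waals radii must be strictly positive and finite")
    tab[toupper(names(overrides))] <- as.numeric(overrides)
  }
  tab
}

vdw_radius <- function(elements, radii = vdw_radius_table()) {
  key <- toupper(elements)
  r <- radii[key]
  if (anyNA(r)) {
    bad <- unique(key[is.na(r)])
    stop("unknown element(s) in van der Waals radius table: ",
         paste(bad, collapse = ", "))
  }
  unname(r)
}

#' Maximum solvent accessibility table
#'
#' Theoretical maximum accessible surface area per residue type (angstrom^2),
#' from the Tien et al. (2013) theoretical values, used to normalise absolute
#' solvent accessibility when deciding whether a residue is buried
#' (ASA / maxASA < 7 percent).
#'
#' @return Named numeric vector, one-letter residue code -> maximum ASA in
#'   angstrom^2.
#' @export
max_asa_table <- function() {
  c(A = 129, R = 274, N = 195, D = 193, C = 167,
    Q = 225, E = 223, G = 104, H = 224, I = 197,
    L = 201, K = 236, M = 224, F = 240, P = 159,
    S = 155, T = 172, W = 285, Y = 263, V = 174)
}

# Canonical heavy-atom counts (N, CA, C, O backbone + side-chain heavy atoms),
# used to flag residues with incomplete side chains in the coordinate model.
heavy_atom_counts <- function() {
  c(A = 5, R = 11, N = 8, D = 8, C = 6,
    Q = 9, E = 9, G = 4, H = 10, I = 8,
    L = 8, K = 9, M = 8, F = 11, P = 7,
    S = 6, T = 7, W = 14, Y = 12, V = 7)
}

#' Amino-acid physicochemical property table
#'
#' The Meiler et al. (2001) seven property scales per amino acid, in the
#' fixed column order: steric parameter, polarizability, volume,
#' hydrophobicity, isoelectric point, helix probability, sheet probability.
#' Embedded so encoding requires no runtime download.
#'
#' @return 20 x 7 numeric matrix, rows named by one-letter code.
#' @export
meiler_table <- function() {
  m <- rbind(
    A = c(1.28, 0.05, 1.00,  0.31,  6.11, 0.42, 0.23),
    R = c(2.34, 0.29, 6.13, -1.01, 10.74, 0.36, 0.25),
    N = c(1.60, 0.13, 2.95, -0.60,  6.52, 0.21, 0.22),
    D = c(1.60, 0.11, 2.78, -0.77,  2.95, 0.25, 0.20),
    C = c(1.77, 0.13, 2.43,  1.54,  6.35, 0.17, 0.41),
    Q = c(1.56, 0.18, 3.95, -0.22,  5.65, 0.36, 0.25),
    E = c(1.56, 0.15, 3.78, -0.64,  3.09, 0.42, 0.21),
    G = c(0.00, 0.00, 0.00,  0.00,  6.07, 0.13, 0.15),
    H = c(2.99, 0.23, 4.66,  0.13,  7.69, 0.27, 0.30),
    I = c(4.19, 0.19, 4.00,  1.80,  6.04, 0.30, 0.45),
    L = c(2.59, 0.19, 4.00,  1.70,  6.04, 0.39, 0.31),
    K = c(1.89, 0.22, 4.77, -0.99,  9.99, 0.32, 0.27),
    M = c(2.35, 0.22, 4.43,  1.23,  5.71, 0.38, 0.32),
    F = c(2.94, 0.29, 5.89,  1.79,  5.67, 0.30, 0.38),
    P = c(2.67, 0.00, 2.72,  0.72,  6.80, 0.13, 0.34),
    S = c(1.31, 0.06, 1.60, -0.04,  5.70, 0.20, 0.28),
    T = c(3.03, 0.11, 2.60,  0.26,  5.60, 0.21, 0.36),
    W = c(3.21, 0.41, 8.08,  2.25,  5.94, 0.32, 0.42),
    Y = c(2.94, 0.30, 6.47,  0.96,  5.66, 0.25, 0.41),
    V = c(3.67, 0.14, 3.00,  1.22,  6.02, 0.27, 0.49))
  colnames(m) <- c("steric", "polarizability", "volume", "hydrophobicity",
                   "isoelectric", "helix_prob", "sheet_prob")
  m
}

#' Rigid-block composition table
#'
#' Binary composition of each residue type in terms of 19 side-chain and
#' backbone rigid blocks (a residue may contain several blocks; glycine
#' carries only the bare backbone block). The decomposition covers small and
#' branched aliphatic units, aromatic rings, amide/carboxylate/guanidinium
#' planar groups, hydroxyl/thiol units, and the ring systems of histidine,
#' tryptophan and proline.
#'
#' @return 20 x 19 integer 0/1 matrix, rows named by one-letter code.
#' @export
psp19_table <- function() {
  blocks <- paste0("B", sprintf("%02d", 1:19))
  aa <- unname(amino_acids())
  m <- matrix(0L, nrow = 20, ncol = 19, dimnames = list(sort(aa), blocks))
  set1 <- function(res, cols) m[res, cols] <<- 1L
  set1("A", 1)                 # methyl
  set1("V", c(1, 2))           # two methyls on branched CB
  set1("L", c(1, 2, 3))        # isobutyl
  set1("I", c(1, 2, 4))        # sec-butyl
  set1("M", c(3, 5))           # methylene chain + thioether
  set1("C", 6)                 # thiol
  set1("S", 7)                 # hydroxyl
  set1("T", c(1, 7))           # methyl + hydroxyl
  set1("F", c(3, 8))           # benzyl
  set1("Y", c(3, 8, 9))        # phenol
  set1("W", c(3, 10))          # indole
  set1("H", c(3, 11))          # imidazole
  set1("D", 12)                # carboxylate
  set1("E", c(3, 12))          # methylene + carboxylate
  set1("N", 13)                # amide
  set1("Q", c(3, 13))          # methylene + amide
  set1("K", c(3, 14, 15))      # butylene + amine
  set1("R", c(3, 14, 16))      # propylene + guanidinium
  set1("P", 17)                # pyrrolidine ring
  set1("G", 18)                # bare backbone
  m[, 19] <- ifelse(rownames(m) == "G", 0L, 1L)  # CB present
  m
}
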