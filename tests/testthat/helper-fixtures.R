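# Hand-written text fixtures (PDB, DSSP, PSSM, HHM) built at test time.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, alt = " ", element = "C") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, occ, 0, element)
}

hetatm_line <- function(serial, resname, chain, resno, x, y, z) {
  sprintf("HETATM%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, " O  ", " ", resname, chain, resno, x, y, z, 1, 0, "O")
}

# single chain, three residues (CA-only), plus a water
write_toy_pdb_single <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    pdb_atom_line(1, " CA ", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, " CA ", "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(3, " CA ", "SER", "A", 3, 7.6, 0, 0),
    hetatm_line(4, "HOH", "A", 101, 20, 20, 20),
    "END")
  writeLines(lines, path)
  path
}

# two chains with a controlled closest C-C contact distance; water in chain B;
# one atom with two altLocs; residue A2 is a complete glycine backbone, all
# other residues are CA-only (incomplete side chains)
write_toy_pdb_pair <- function(contact_dist, path = tempfile(fileext = ".pdb")) {
  lines <- c(
    pdb_atom_line(1, " CA ", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, " N  ", "GLY", "A", 2, -1.0, 3.3, 0, element = "N"),
    pdb_atom_line(3, " CA ", "GLY", "A", 2, 0, 3.8, 0),
    pdb_atom_line(4, " C  ", "GLY", "A", 2, 0.8, 4.3, 0),
    pdb_atom_line(5, " O  ", "GLY", "A", 2, 0.6, 5.4, 0, element = "O"),
    pdb_atom_line(6, " CA ", "LEU", "B", 1, contact_dist, 0, 0, occ = 0.6, alt = "A"),
    pdb_atom_line(7, " CA ", "LEU", "B", 1, contact_dist + 50, 0, 0, occ = 0.4, alt = "B"),
    pdb_atom_line(8, " CA ", "VAL", "B", 2, contact_dist, 0, 3.8),
    hetatm_line(9, "HOH", "B", 101, 30, 30, 30),
    "END")
  writeLines(lines, path)
  path
}

dssp_residue_line <- function(i, resno, chain, aa, ss, acc) {
  paste0(sprintf("%5d", i), sprintf("%5d", resno), " ", chain, " ", aa,
         "  ", ss, strrep(" ", 17), sprintf("%4d", acc))
}

dssp_break_line <- function(i) {
  paste0(sprintf("%5d", i), strrep(" ", 8), "!")
}

write_toy_dssp <- function(rows, path = tempfile(fileext = ".dssp")) {
  header <- c(
    "==== Secondary Structure Definition by the program DSSP  ====",
    "REFERENCE ...",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA")
  writeLines(c(header, rows), path)
  path
}

# PSI-BLAST ASCII PSSM with given integer score matrix (L x 20)
write_toy_pssm <- function(sequence, scores, path = tempfile(fileext = ".pssm")) {
  aa_cols <- c("A","R","N","D","C","Q","E","G","H","I",
               "L","K","M","F","P","S","T","W","Y","V")
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", c(aa_cols, aa_cols)), collapse = " ")))
  chars <- strsplit(sequence, "")[[1]]
  for (i in seq_along(chars)) {
    lines <- c(lines, paste0(
      sprintf("%5d %s  ", i, chars[i]),
      paste(sprintf("%3d", scores[i, ]), collapse = " "), "  ",
      paste(sprintf("%3d", rep(0, 20)), collapse = " "),
      "  0.00 0.00"))
  }
  writeLines(c(lines, "", "                      K         Lambda"), path)
  path
}

# HHblits HHM file with given integer emission scores (L x 20, NA = '*') and
# transition scores (L x 10)
write_toy_hhm <- function(sequence, emissions, transitions,
                          path = tempfile(fileext = ".hhm")) {
  tok <- function(v) paste(ifelse(is.na(v), "*", as.character(v)), collapse = "\t")
  chars <- strsplit(sequence, "")[[1]]
  lines <- c(
    "HHsearch 1.5",
    "NAME  toy",
    paste("LENG ", length(chars), "match states"),
    "NULL   3706	5728	4211	4064	4839	3729	4763	4308	4069	3323	5509	4640	4464	4937	4285	4423	3815	3783	6325	4665",
    "HMM    A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y",
    "       M->M	M->I	M->D	I->M	I->I	D->M	D->D	Neff	Neff_I	Neff_D",
    paste0("       ", tok(c(0, rep(NA, 6), 1000, 0, 0))))
  for (i in seq_along(chars)) {
    lines <- c(lines,
               paste0(chars[i], " ", i, "\t", tok(emissions[i, ]), "\t", i),
               paste0("       ", tok(transitions[i, ])))
  }
  writeLines(c(lines, "//"), path)
  path
}
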