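# Structure parsing, interface contacts, DSSP parsing, secondary-structure
# mapping, the buried rule, accessibility, and annotation assembly.

test_that("parse_structure keeps protein atoms, drops waters, resolves altLocs", {
  s1 <- parse_structure(write_toy_pdb_single())
  expect_length(s1$chains, 1)
  expect_equal(nrow(s1$chains$A$residues), 3)
  expect_equal(s1$chains$A$residues$aa, c("A", "G", "S"))
  # water excluded from both chains of the pair fixture
  s2 <- parse_structure(write_toy_pdb_pair(3.85))
  expect_equal(names(s2$chains), c("A", "B"))
  expect_false(any(s2$chains$B$residues$resid == "HOH"))
  # altLoc A (occupancy 0.6) retained, B (0.4) dropped
  b_res1 <- s2$chains$B$atoms[s2$chains$B$atoms$resno == 1, ]
  expect_equal(nrow(b_res1), 1)
  expect_equal(b_res1$x, 3.85)
})

test_that("interface labels follow the vdW + pad contact rule", {
  # closest inter-chain C-C pair at 3.85 A; threshold 1.7 + 1.7 + 0.5 = 3.9
  s <- parse_structure(write_toy_pdb_pair(3.85))
  lab <- compute_interface_labels(s)
  expect_equal(lab$A, c(1L, 0L))
  expect_equal(lab$B, c(1L, 0L))
  # at 3.95 A the same geometry yields no contact
  s_far <- parse_structure(write_toy_pdb_pair(3.95))
  lab_far <- compute_interface_labels(s_far)
  expect_equal(unname(unlist(lab_far)), rep(0L, 4))
  # chains 100 A apart: everything 0
  s_apart <- parse_structure(write_toy_pdb_pair(100))
  expect_true(all(unlist(compute_interface_labels(s_apart)) == 0))
})

test_that("single-chain structures have undefined interface labels", {
  s <- parse_structure(write_toy_pdb_single())
  expect_warning(lab <- compute_interface_labels(s), "single-chain")
  expect_true(all(is.na(lab$A)))
})

test_that("interface labeling matches the brute-force oracle and is monotone in pad", {
  for (seed in 1:6) {
    tc <- generate_toy_complex(n_chains = sample(2:4, 1),
                               residues_per_chain = sample(4:10, 1),
                               seed = seed)
    path <- tempfile(fileext = ".pdb")
    writeLines(tc$pdb_lines, path)
    s <- parse_structure(path)
    impl <- compute_interface_labels(s)
    oracle <- brute_force_interface(s)
    expect_equal(unname(impl), unname(oracle))
    # symmetry: any labeled residue has a labeled partner in another chain
    if (sum(unlist(impl)) > 0) expect_gte(sum(unlist(impl)), 2)
    # pad monotonicity: interface set grows with pad
    wider <- compute_interface_labels(s, pad = 2.0)
    expect_true(all(unlist(impl) <= unlist(wider)))
  }
})

test_that("parse_dssp reads structure codes, accessibility and chain breaks", {
  rows <- c(dssp_residue_line(1, 1, "A", "M", "H", 120),
            dssp_residue_line(2, 2, "A", "A", " ", 45),
            dssp_break_line(3),
            dssp_residue_line(4, 1, "B", "G", "E", 80))
  d <- parse_dssp(write_toy_dssp(rows))
  expect_equal(nrow(d), 3)  # the break marker emits no residue
  expect_equal(d$s8, c("H", "C", "E"))  # blank structure code is coil
  expect_equal(d$asa, c(120, 45, 80))
  expect_equal(d$chain, c("A", "A", "B"))
})

test_that("the S8 to S3 mapping is the stated partition", {
  expect_equal(map_s8_to_s3("B"), "E")
  expect_equal(map_s8_to_s3("G"), "H")
  expect_equal(map_s8_to_s3("C"), "C")
  mapped <- map_s8_to_s3(s8_classes())
  # total: every S8 class maps to exactly one S3 class
  expect_length(mapped, 8)
  expect_true(all(mapped %in% s3_classes()))
  # the three preimages are disjoint and cover all 8 classes
  pre <- split(s8_classes(), mapped)
  expect_setequal(names(pre), s3_classes())
  expect_equal(sort(unlist(pre, use.names = FALSE)), sort(s8_classes()))
  expect_setequal(pre$C, c("C", "S", "T"))
  expect_setequal(pre$H, c("H", "G", "I"))
  expect_setequal(pre$E, c("E", "B"))
  expect_error(map_s8_to_s3("X"), "unknown")
})

test_that("the buried rule uses a strict 7 percent threshold", {
  expect_equal(compute_buried_label(0, "A"), 1L)
  for (aa in c("A", "G", "W", "V")) {
    max_asa <- max_asa_table()[[aa]]
    for (rel in c(0.0699, 0.07, 0.071, 0.01)) {
      asa <- rel * max_asa
      expected <- as.integer(asa / max_asa < 0.07)  # scalar oracle
      expect_identical(compute_buried_label(asa, aa), expected)
    }
  }
  # monotone non-increasing in asa for a fixed residue type
  asa_grid <- seq(0, 30, by = 0.5)
  lab <- compute_buried_label(asa_grid, rep("G", length(asa_grid)))
  expect_true(all(diff(lab) <= 0))
  expect_error(compute_buried_label(10, "Z"), "unknown residue")
})

test_that("Shrake-Rupley area is exact for an isolated atom", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, " CA ", "ALA", "A", 1, 0, 0, 0), "END"), path)
  s <- parse_structure(path)
  asa <- shrake_rupley_asa(s)
  expect_equal(asa$asa, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-10)
})

test_that("build_annotations sets labels and masks per the masking rules", {
  s <- parse_structure(write_toy_pdb_pair(3.85))
  rows <- c(dssp_residue_line(1, 1, "A", "A", "H", 50),
            dssp_residue_line(2, 2, "A", "G", "E", 7),
            dssp_residue_line(3, 1, "B", "L", " ", 100),
            dssp_residue_line(4, 2, "B", "V", "T", 60))
  ann <- build_annotations(s, parse_dssp(write_toy_dssp(rows)),
                           ppi_available = TRUE)
  expect_equal(ann$IF, c(1L, 0L, 1L, 0L))
  expect_equal(ann$S8, c("H", "E", "C", "T"))
  expect_equal(ann$S3, c("H", "E", "C", "C"))
  expect_equal(ann$SA[2], 7)
  expect_equal(ann$BU[2], compute_buried_label(7, "G"))
  # incomplete residues (fewer heavy atoms than canonical) are SA/BU masked
  expect_false(ann$mask_SA[1])           # ALA with 1 of 5 atoms
  expect_true(ann$mask_SA[2])            # complete glycine backbone (4 of 4)
  expect_equal(ann$mask_BU, ann$mask_SA) # BU missing whenever SA missing
  # no PPI annotation: interface fully masked, structural tasks unaffected
  ann2 <- build_annotations(s, parse_dssp(write_toy_dssp(rows)),
                            ppi_available = FALSE)
  expect_true(all(!ann2$mask_IF))
  expect_true(all(is.na(ann2$IF)))
  expect_equal(ann2$mask_S3, ann$mask_S3)
})

test_that("annotation TSV writes missing values as dots", {
  s <- parse_structure(write_toy_pdb_pair(3.85))
  rows <- c(dssp_residue_line(1, 1, "A", "A", "H", 50),
            dssp_residue_line(2, 2, "A", "G", "E", 7),
            dssp_residue_line(3, 1, "B", "L", " ", 100),
            dssp_residue_line(4, 2, "B", "V", "T", 60))
  ann <- build_annotations(s, parse_dssp(write_toy_dssp(rows)),
                           ppi_available = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_annotations_tsv(ann, path)
  got <- utils::read.delim(path, colClasses = "character")
  expect_equal(got$IF, rep(".", 4))
  expect_equal(got$S8, c("H", "E", "C", "T"))
})
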