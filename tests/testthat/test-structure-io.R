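test_that("write/read round trip preserves residues and coordinates", {
  fx <- buildHLH(hlhRecipe(helix1 = 11, loop = 5, helix2 = 11,
                           cys_positions = c(3, 25),
                           ss_pairs = matrix(c(3L, 25L), ncol = 2)),
                 id = "rt")
  f <- tempfile(fileext = ".pdb")
  writeStructure(fx$structure, f)
  s2 <- readStructure(f)
  rt1 <- residueTable(fx$structure)
  rt2 <- residueTable(s2)
  expect_equal(nrow(rt2), 27L)
  expect_identical(rt2$label_id, 1:27)
  expect_identical(rt2$resid, rt1$resid)
  expect_identical(s2@atoms$elety, fx$structure@atoms$elety)
  expect_lt(max(abs(as.matrix(s2@atoms[, c("x", "y", "z")]) -
                    as.matrix(fx$structure@atoms[, c("x", "y", "z")]))),
            1e-3)
})

test_that("altloc resolves to highest occupancy, ties by file order", {
  pdb <- c(
    "ATOM      1  CA ASER A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA AVAL A   2       3.800   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BVAL A   2       9.900   0.000   0.000  0.40  0.00           C",
    "ATOM      4  CA ATHR A   3       7.600   0.000   0.000  0.50  0.00           C",
    "ATOM      5  CA BTHR A   3      99.000   0.000   0.000  0.50  0.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  s <- readStructure(f)
  ca <- caCoords(s, "A")
  expect_equal(nrow(ca), 3L)
  expect_equal(ca[2, "x"], 3.8)    # occupancy 0.6 wins over 0.4
  expect_equal(ca[3, "x"], 7.6)    # tie 0.5/0.5 -> first in file
})

test_that("label_id is a gap-free 1..n index over author-numbering gaps", {
  atoms <- data.frame(chain = "A", resno = c(10L, 11L, 20L, 21L, 35L),
                      resid = "ALA", elety = "CA",
                      x = 3.8 * (0:4), y = 0, z = 0)
  s <- PolymerStructure("gaps", atoms)
  rt <- residueTable(s, "A")
  expect_identical(rt$label_id, 1:5)
  expect_identical(rt$resno, c(10L, 11L, 20L, 21L, 35L))
})

test_that("waters and ligands are dropped, norleucine survives as Z", {
  pdb <- c(
    "ATOM      1  CA  SER A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  CA  NLE A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  THR A   3       7.600   0.000   0.000  1.00  0.00           C",
    "HETATM    4  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O",
    "HETATM    5 ZN    ZN A 201      25.000  25.000  25.000  1.00  0.00          ZN",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  s <- readStructure(f)
  expect_equal(chainSequence(s, "A"), "SZT")
})

test_that("mmCIF input parses with author numbering and water removal", {
  cif <- c(
    "data_mini", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")),
    "ATOM 1 C CA . SER A 1 1 ? 1.0 2.0 3.0 1.00 0.00 ? 5 SER A CA 1",
    "ATOM 2 C CA . VAL A 1 2 ? 4.5 2.5 3.5 1.00 0.00 ? 6 VAL A CA 1",
    "ATOM 3 C CA . NLE A 1 3 ? 8.0 3.0 4.0 1.00 0.00 ? 7 NLE A CA 1",
    "ATOM 4 O O . HOH B 2 . ? 20.0 20.0 20.0 1.00 0.00 ? 101 HOH B O 1")
  f <- tempfile(fileext = ".cif")
  writeLines(cif, f)
  s <- readStructure(f)
  expect_equal(chainSequence(s, "A"), "SVZ")
  expect_identical(residueTable(s, "A")$resno, 5:7)
})

test_that("unreadable and empty inputs raise informative errors", {
  expect_error(readStructure(tempfile()), "not found")
  f <- tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
               "END"), f)
  expect_error(readStructure(f), "no polymer")
})

test_that("chain sequence and findSubsequence behave on strings and structures", {
  expect_equal(findSubsequence("ABCDE", "CD"), 3L)
  expect_true(is.na(findSubsequence("ABCDE", "XY")))
  expect_error(findSubsequence("", "A"))

  atoms <- data.frame(chain = "A", resno = 28:41,
                      resid = c("SER", "VAL", "THR", "GLU", "GLN", "GLY",
                                "ALA", "GLU", "LEU", "SER", "ASN", "GLU",
                                "GLU", "ARG"),
                      elety = "CA", x = 3.8 * (0:13), y = 0, z = 0)
  s <- PolymerStructure("frag", atoms)
  expect_equal(chainSequence(s, "A"), "SVTEQGAELSNEER")
  hit <- findSubsequence(s, "EQGAELS", "A")
  expect_true(hit$found)
  expect_equal(hit$auth_start, 31L)  # author numbering, not label_id
  expect_equal(hit$label_start, 4L)
  miss <- findSubsequence(s, "WWW", "A")
  expect_false(miss$found)
  expect_error(chainSequence(s, "B"), "chain")
})

test_that("PDB writer enforces format capacity", {
  fx <- buildHLH(hlhRecipe(6, 2, 6))
  s <- fx$structure
  s@atoms$x[1] <- 10500
  expect_error(writeStructure(s, tempfile(fileext = ".pdb")),
               "field width")
  big <- fx$structure
  big@atoms <- big@atoms[rep(seq_len(nrow(big@atoms)),
                             length.out = 100001L), ]
  big@atoms$label_id <- rep(1L, 100001L)
  big@atoms$resno <- 1L
  expect_error(writeStructure(big, tempfile(fileext = ".pdb")),
               "format capacity")
})
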