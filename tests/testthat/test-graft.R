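test_that("splicing reproduces the published loop grafts", {
  sc <- vhtiScaffold()
  # replacing residues 9-14 with the A-prefixed epitope window
  d2 <- buildChimera(sc, c(9, 14), "AQGAEL", "VhTI-pep 2")
  expect_equal(peptideSequence(d2), "EQCKVZCYAQGAELPELLRRCLDNCEK")
  d1 <- buildChimera(sc, c(9, 14), "AQGAELS", "VhTI-pep 1")
  expect_equal(nchar(peptideSequence(d1)), 28L)
  expect_equal(peptideSequence(d1), unname(PUBLISHED_SEQS["VhTI-pep 1"]))
  # chimera inherits terminal modifications and disulfide count
  expect_equal(d2@chimera@nTerm, "acetyl")
  expect_equal(d2@chimera@cTerm, "amide")
  expect_equal(d2@chimera@nDisulfides, 2L)

  # identity splice
  ident <- buildChimera(sc, c(9, 14),
                        substr(peptideSequence(sc), 9, 14), "ident")
  expect_equal(peptideSequence(ident), peptideSequence(sc))

  expect_error(buildChimera(sc, c(0, 5), "AAA"), "span")
  expect_error(buildChimera(sc, c(9, 28), "AAA"), "span")
  expect_error(buildChimera(sc, c(9, 14), "AQB1"), "invalid residue")
  expect_warning(buildChimera(sc, c(9, 14), "ACA"), "cysteine")
})

test_that("splicing is local and length bookkeeping is exact", {
  sc <- vhtiScaffold()
  set.seed(42)
  aas <- strsplit("ADEFGHIKLNPQRSTVWY", "")[[1]]
  for (i in 1:25) {
    st <- sample(8:14, 1)
    en <- st + sample.int(15 - st, 1) - 1L
    ins <- paste(sample(aas, sample(0:8, 1), replace = TRUE),
                 collapse = "")
    d <- buildChimera(sc, c(st, en), ins)
    expect_equal(nchar(peptideSequence(d)),
                 27L - (en - st + 1L) + nchar(ins))
    expect_equal(substr(peptideSequence(d), 1, st - 1),
                 substr(peptideSequence(sc), 1, st - 1))
    n_tail <- 27L - en
    expect_equal(substr(peptideSequence(d),
                        nchar(peptideSequence(d)) - n_tail + 1,
                        nchar(peptideSequence(d))),
                 substr(peptideSequence(sc), en + 1, 27))
  }
})

test_that("register enumeration yields distinct chimeras and merges duplicates", {
  sc <- vhtiScaffold()
  # contiguous windows of the loop epitope produce the pep 1-4 series
  ds_a <- enumerateDesigns(sc, c(10, 14), "EQGAELS",
                           data.frame(offset = c(2, 2), length = c(6, 5)))
  expect_equal(vapply(ds_a, peptideSequence, character(1)),
               unname(PUBLISHED_SEQS[c("VhTI-pep 2", "VhTI-pep 1")]),
               ignore_attr = TRUE)
  ds_b <- enumerateDesigns(sc, c(9, 14), "EQGAELS",
                           data.frame(offset = c(1, 2), length = c(6, 6)))
  expect_equal(sort(vapply(ds_b, peptideSequence, character(1))),
               sort(unname(PUBLISHED_SEQS[c("VhTI-pep 3", "VhTI-pep 4")])))

  # identical windows collapse with merged provenance
  dup <- enumerateDesigns(sc, c(9, 14), "EQGAELS",
                          data.frame(offset = c(1, 1), length = c(6, 6)))
  expect_length(dup, 1L)
  expect_length(dup[[1]]@provenance, 2L)

  expect_error(enumerateDesigns(sc, c(9, 14), "EQGAELS",
                                data.frame(offset = 3, length = 6)),
               "bounds")
  expect_error(enumerateDesigns(sc, c(9, 14), "EQGAELS",
                                data.frame(offset = integer(0),
                                           length = integer(0))),
               "non-empty")
})

test_that("single-residue substitution is exact and validated", {
  native <- PeptideSpec("EQCKVMCYAQRHSSPELLRRCLDNCEK", n_term = "acetyl",
                        c_term = "amide", n_disulfides = 2L)
  nor <- applySubstitution(native, 6, "Z")
  expect_equal(peptideSequence(nor), peptideSequence(vhtiScaffold()))
  expect_equal(nor@nTerm, "acetyl")
  same <- applySubstitution(native, 6, "M")
  expect_equal(peptideSequence(same), peptideSequence(native))
  expect_error(applySubstitution(native, 0, "A"), "position")
  expect_error(applySubstitution(native, 3, "B"), "invalid residue")
})

test_that("the packaged design config reproduces the published series", {
  ds <- vhtiDesigns()
  expect_named(ds, names(PUBLISHED_SEQS))
  for (nm in names(PUBLISHED_SEQS))
    expect_equal(peptideSequence(ds[[nm]]), unname(PUBLISHED_SEQS[nm]))
  ref <- attr(ds, "reference")
  expect_equal(nchar(peptideSequence(ref$pepitem)), 14L)
  sc <- attr(ds, "scaffold")
  expect_equal(peptideSequence(sc), peptideSequence(vhtiScaffold()))
  # every chimera keeps the scaffold's four cysteines and modifications
  for (d in ds) {
    expect_equal(sum(strsplit(peptideSequence(d), "")[[1]] == "C"), 4L)
    expect_equal(d@chimera@nTerm, "acetyl")
    expect_equal(d@chimera@cTerm, "amide")
    expect_equal(d@chimera@nDisulfides, 2L)
  }
})

test_that("peptide specs validate their alphabet and disulfide budget", {
  expect_error(PeptideSpec("ABCD"), "invalid residue")
  expect_error(PeptideSpec(""), "non-empty")
  expect_error(PeptideSpec("ACCA", n_disulfides = 2L), "exceeds")
  p <- PeptideSpec("ACCA", n_disulfides = 1L)
  expect_s4_class(p, "PeptideSpec")
})
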