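mk_labels <- function(spec) {
  # spec like c(H = 10, C = 5, H = 10)
  new("SecStructAssignment",
      labels = rep(names(spec), spec), chain = "A", parameters = list())
}

test_that("motif extraction finds helix pairs over short gaps", {
  m1 <- extractHLHMotifs(mk_labels(c(H = 10, C = 5, H = 10)), source = "x")
  expect_length(m1, 1L)
  expect_equal(diff(m1[[1]]@loop) + 1L, 5L)
  expect_equal(m1[[1]]@helix1, c(1L, 10L))
  expect_equal(m1[[1]]@helix2, c(16L, 25L))

  expect_length(extractHLHMotifs(mk_labels(c(H = 12))), 0L)
  # three helices, gaps 4 and 4 -> two motifs
  m3 <- extractHLHMotifs(mk_labels(c(H = 10, C = 4, H = 10, C = 4, H = 10)))
  expect_length(m3, 2L)
  # gap beyond the loop cap is not a turn
  expect_length(extractHLHMotifs(mk_labels(c(H = 10, C = 13, H = 10))), 0L)
  # E counts as a non-helix gap
  expect_length(extractHLHMotifs(mk_labels(c(H = 10, E = 3, H = 10))), 1L)
})

test_that("motif extraction on a built fixture matches ground truth", {
  fx <- buildHLH(hlhRecipe(10, 5, 10))
  ms <- extractHLHMotifs(assignSecStruct(fx$structure, "A"), source = "fx")
  expect_length(ms, 1L)
  expect_equal(ms[[1]]@helix1, fx$motif@helix1)
  expect_equal(ms[[1]]@loop, fx$motif@loop)
  expect_equal(ms[[1]]@helix2, fx$motif@helix2)
})

test_that("disulfide detection recovers planted staples with Roman naming", {
  fx <- buildHLH(hlhRecipe(10, 5, 10, cys_positions = c(2, 4, 22, 24),
                           ss_pairs = rbind(c(2L, 24L), c(4L, 22L))))
  dp <- detectDisulfides(fx$structure, "A")
  expect_equal(dp@roman, "I–IV, II–III")
  expect_equal(unname(dp@pairs[, "i"]), c(1L, 2L))
  expect_equal(unname(dp@pairs[, "j"]), c(4L, 3L))

  # invariance under rigid transform
  s <- fx$structure
  set.seed(3)
  R <- random_rotation()
  xyz <- as.matrix(s@atoms[, c("x", "y", "z")]) %*% t(R)
  s@atoms[, c("x", "y", "z")] <- sweep(xyz, 2, c(5, -7, 12), "+")
  expect_equal(detectDisulfides(s, "A")@roman, dp@roman)
})

test_that("disulfide detection respects distance thresholds and fallbacks", {
  expect_equal(nrow(detectDisulfides(
    buildHLH(hlhRecipe(6, 2, 6))$structure, "A")@pairs), 0L)

  # two cysteines with S-gamma 6 A apart: no bond
  atoms <- data.frame(
    chain = "A",
    resno = c(1L, 1L, 2L, 2L),
    resid = "CYS",
    elety = c("CA", "SG", "CA", "SG"),
    x = c(0, 1, 8, 7), y = 0, z = 0)
  s <- PolymerStructure("far", atoms)
  expect_equal(nrow(detectDisulfides(s, "A")@pairs), 0L)

  # missing S-gamma falls back to C-beta within 4.5 A
  atoms2 <- data.frame(
    chain = "A", resno = c(1L, 1L, 2L, 2L), resid = "CYS",
    elety = c("CA", "CB", "CA", "CB"),
    x = c(0, 1.5, 6.5, 5.0), y = 0, z = 0)
  dp2 <- detectDisulfides(PolymerStructure("cb", atoms2), "A")
  expect_equal(nrow(dp2@pairs), 1L)
  expect_equal(dp2@roman, "I–II")
})

test_that("the curation filter applies inclusive bounds with reason codes", {
  expect_true(scaffoldFilter(27, 4)$pass)     # VhTI-like
  f14 <- scaffoldFilter(14, 0)                # pepitem: no cysteines
  expect_false(f14$pass)
  expect_equal(f14$reasons, "too_few_cys")
  f9 <- scaffoldFilter(9, 2)
  expect_equal(f9$reasons, "too_short")
  expect_true(scaffoldFilter(10, 2)$pass)     # boundaries inclusive
  expect_true(scaffoldFilter(50, 2)$pass)
  expect_equal(scaffoldFilter(51, 2)$reasons, "too_long")
  expect_false(scaffoldFilter(8, 0)$pass)
  expect_setequal(scaffoldFilter(8, 0)$reasons,
                  c("too_short", "too_few_cys"))
})

test_that("filtering is a pure function: permutation leaves survivors unchanged", {
  lib <- buildLibrary(n = 12, seed = 4)
  cands <- lapply(lib$structures, scaffoldCandidate)
  pass1 <- sort(names(Filter(function(cd) scaffoldFilter(cd)$pass, cands)))
  set.seed(9)
  pass2 <- sort(names(Filter(function(cd) scaffoldFilter(cd)$pass,
                             sample(cands))))
  expect_identical(pass1, pass2)
})

test_that("deduplication keeps one candidate per sequence, smallest source", {
  mk <- function(src, seq) new("ScaffoldCandidate", source = src,
    chain = "A", sequence = seq, length = nchar(seq),
    nCys = sum(strsplit(seq, "")[[1]] == "C"),
    motif = list(),
    disulfides = new("DisulfidePattern",
                     pairs = matrix(integer(0), ncol = 2), roman = ""))
  a <- mk("2XYZ", "ACDEFGHIKL")
  b <- mk("1ABC", "ACDEFGHIKL")
  d <- dedupeCandidates(list(a, b))
  expect_length(d, 1L)
  expect_equal(d[[1]]@source, "1ABC")

  expect_length(dedupeCandidates(list()), 0L)

  five <- list(mk("S1", "AAAA"), mk("S2", "CCCC"), mk("S3", "AAAA"),
               mk("S4", "DDDD"), mk("S5", "CCCC"))
  expect_length(dedupeCandidates(five), 3L)
})
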