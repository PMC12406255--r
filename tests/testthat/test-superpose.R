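test_that("kabsch recovers exact rigid transforms", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  r0 <- kabsch(P, P)
  expect_lt(r0@rmsd, 1e-12)
  expect_equal(r0@rotation, diag(3), tolerance = 1e-9)

  for (s in 1:20) {
    set.seed(s)
    P <- matrix(rnorm(30), 10, 3)
    R <- random_rotation()
    tr <- runif(3, -10, 10)
    Q <- sweep(P %*% t(R), 2, tr, "+")
    fit <- kabsch(P, Q)
    expect_lt(fit@rmsd, 1e-9)
    expect_lt(max(abs(applyTransform(fit, P) - Q)), 1e-8)
    expect_equal(det(fit@rotation), 1, tolerance = 1e-9)
  }
})

test_that("kabsch agrees with the quaternion (Horn) oracle", {
  deltas <- vapply(1:100, function(s) {
    set.seed(s)
    P <- matrix(rnorm(30), 10, 3)
    Q <- matrix(rnorm(30), 10, 3)
    abs(kabsch(P, Q)@rmsd - horn_rmsd(P, Q))
  }, numeric(1))
  expect_lt(max(deltas), 1e-8)
})

test_that("RMSD is symmetric and invariant under common rigid transforms", {
  for (s in 1:10) {
    set.seed(s)
    P <- matrix(rnorm(24), 8, 3)
    Q <- matrix(rnorm(24), 8, 3)
    expect_lt(abs(kabsch(P, Q)@rmsd - kabsch(Q, P)@rmsd), 1e-9)
    R <- random_rotation()
    tr <- runif(3, -5, 5)
    Pt <- sweep(P %*% t(R), 2, tr, "+")
    Qt <- sweep(Q %*% t(R), 2, tr, "+")
    expect_lt(abs(kabsch(P, Q)@rmsd - kabsch(Pt, Qt)@rmsd), 1e-9)
  }
})

test_that("degenerate inputs are flagged or rejected", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  line <- cbind(0:4 * 3.8, 0, 0)
  fit <- kabsch(line, line)
  expect_true(fit@details$ill_conditioned)
})

test_that("framework alignment is exact on rigid-transformed copies", {
  fx <- buildHLH(hlhRecipe(10, 5, 10), id = "q")
  fy <- buildHLH(hlhRecipe(10, 5, 10, transform = TRUE, seed = 5),
                 id = "c")
  res <- frameworkAlign(fx$structure, fx$motif, fy$structure, fy$motif)
  expect_lt(res@rmsd, 1e-9)
  expect_lt(res@details$loop_rmsd, 1e-9)
  expect_equal(res@details$aligned_length, 20L)
  # correspondence strictly increasing in both columns
  expect_true(all(diff(res@correspondence[, 1]) > 0))
  expect_true(all(diff(res@correspondence[, 2]) > 0))
})

test_that("joint offset optimization finds the phase-shifted register", {
  # candidate helix2 has one extra N-terminal residue: the true register is
  # offset 1, not the end-anchored offset 0
  fx <- buildHLH(hlhRecipe(10, 5, 11), id = "long")
  qm <- new("HLHMotif", chain = "A", helix1 = c(1L, 10L),
            loop = c(11L, 16L), helix2 = c(17L, 26L), source = "q")
  res <- frameworkAlign(fx$structure, qm, fx$structure, fx$motif)
  expect_equal(res@details$offsets, c(0, 1))
  expect_lt(res@rmsd, 1e-9)
  # oracle: enumerate both helix2 offsets by direct Kabsch
  ca <- caCoords(fx$structure, "A")
  rms_off <- vapply(0:1, function(o) {
    kabsch(ca[c(1:10, 17:26), ], ca[c(1:10, 16:25 + o), ])@rmsd
  }, numeric(1))
  expect_equal(which.min(rms_off) - 1L, 1L)
  expect_equal(res@rmsd, min(rms_off), tolerance = 1e-9)
})

test_that("framework alignment never loses to an end-anchored pairing", {
  for (s in 1:10) {
    q <- buildHLH(hlhRecipe(10, 4, 10, noise_sigma = 0.3, seed = s))
    c2 <- buildHLH(hlhRecipe(12, 4, 11, noise_sigma = 0.3, seed = s + 50))
    res <- frameworkAlign(q$structure, q$motif, c2$structure, c2$motif)
    qca <- caCoords(q$structure, "A")
    cca <- caCoords(c2$structure, "A")
    naive <- kabsch(qca[c(1:10, 15:24), ], cca[c(1:10, 17:26), ])
    expect_lte(res@rmsd, naive@rmsd + 1e-9)
  }
})

test_that("ce-style alignment handles identity, noise and negatives", {
  fx <- buildHLH(hlhRecipe(10, 5, 10))
  ca <- caCoords(fx$structure, "A")
  same <- ceStyleAlign(ca, ca)
  expect_lt(same@rmsd, 1e-9)
  expect_gte(nrow(same@correspondence), 24L)  # full-length fragment path

  # unrelated random coils: no alignment, or a poor one
  bad <- vapply(1:10, function(s) {
    set.seed(s)
    A <- random_coil(20); B <- random_coil(20)
    res <- ceStyleAlign(A, B)
    if (!isTRUE(res@details$aligned)) Inf else res@rmsd
  }, numeric(1))
  expect_true(all(bad > 1.0))

  # helix vs noisy helix: rmsd tracks the planted coordinate noise
  band <- vapply(1:50, function(s) {
    h <- helixCoords(18)
    set.seed(s)
    hn <- h + matrix(rnorm(54, sd = 0.3 / sqrt(3)), 18, 3)
    ceStyleAlign(h, hn)@rmsd
  }, numeric(1))
  expect_gte(median(band), 0.2)
  expect_lte(median(band), 0.5)
  expect_lt(max(band), 0.5)
})

test_that("candidate ranking orders by fit and skips motif-free entries", {
  q <- buildHLH(hlhRecipe(10, 5, 10), id = "query")
  copy <- buildHLH(hlhRecipe(10, 5, 10, transform = TRUE, seed = 2),
                   id = "copy")
  noisy <- buildHLH(hlhRecipe(10, 5, 10, noise_sigma = 0.8, seed = 3),
                    id = "noisy")
  lib <- list(list(structure = copy$structure, motif = copy$motif,
                   source = "copy"),
              list(structure = noisy$structure, motif = noisy$motif,
                   source = "noisy"),
              list(structure = noisy$structure, motif = NULL,
                   source = "nomotif"))
  tab <- suppressMessages(
    rankCandidates(q$structure, q$motif, lib, mode = "framework"))
  expect_equal(tab$source[1], "copy")
  expect_lt(tab$rmsd[1], 1e-9)
  expect_equal(nrow(tab), 2L)
  expect_match(attr(tab, "skipped"), "nomotif")
})

test_that("ranking tracks conformational deviation across a noise ladder", {
  sig <- 0.05 * 1.45^(0:9)
  good <- 0L
  for (s in 1:50) {
    q <- buildHLH(hlhRecipe(10, 5, 10))
    lib <- lapply(1:10, function(i) {
      fx <- buildHLH(hlhRecipe(10, 5, 10, noise_sigma = sig[i],
                               seed = s * 100 + i))
      list(structure = fx$structure, motif = fx$motif,
           source = sprintf("n%02d", i))
    })
    tab <- rankCandidates(q$structure, q$motif, lib, mode = "framework")
    good <- good + identical(tab$source, sprintf("n%02d", 1:10))
  }
  expect_gte(good, 45L)  # >= 95% of seeds in rank order
})
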