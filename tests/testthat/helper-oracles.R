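# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths.

# Horn's closed-form quaternion solution for the optimal rigid
# superposition RMSD: the optimal rotation corresponds to the largest
# eigenvalue of the 4x4 quaternion matrix built from the cross-covariance.
horn_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,      Szx - Sxz,      Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,     Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,      Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

# Random proper rotation (QR-based), for transform-invariance tests.
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Elemental-composition mass oracle: residue formulas (C,H,N,O,S) summed,
# plus H2O, acetyl (+C2H2O), amide (OH -> NH2) and -2H per disulfide.
# Independent of the package's residue-mass tables.
elemental_mono_mass <- function(sequence, n_term = "free", c_term = "free",
                                n_disulfides = 0) {
  f <- list( # residue formulas: C, H, N, O, S
    G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0),
    Z = c(6, 11, 1, 1, 0))  # norleucine = C6H11NO
  iso <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
           O = 15.9949146196, S = 31.97207100)
  tot <- Reduce(`+`, f[strsplit(sequence, "")[[1]]])
  tot <- tot + c(0, 2, 0, 1, 0)                      # + H2O
  if (n_term == "acetyl") tot <- tot + c(2, 2, 0, 1, 0)
  if (c_term == "amide") tot <- tot + c(0, 1, 1, -1, 0)
  tot <- tot - c(0, 2 * n_disulfides, 0, 0, 0)
  sum(tot * iso[c("C", "H", "N", "O", "S")])
}

# Random-coil C-alpha trace: self-avoiding-ish random walk with 3.8 A steps.
random_coil <- function(n, step = 3.8) {
  X <- matrix(0, n, 3)
  for (i in 2:n) {
    u <- rnorm(3)
    X[i, ] <- X[i - 1, ] + step * u / sqrt(sum(u^2))
  }
  X
}

# The published VhTI chimera series and its calculated masses, used as
# reference points across the suite.
PUBLISHED_SEQS <- c(
  "VhTI-pep 1" = "EQCKVZCYAQGAELSPELLRRCLDNCEK",
  "VhTI-pep 2" = "EQCKVZCYAQGAELPELLRRCLDNCEK",
  "VhTI-pep 3" = "EQCKVZCYEQGAELPELLRRCLDNCEK",
  "VhTI-pep 4" = "EQCKVZCYQGAELSPELLRRCLDNCEK",
  "VhTI-pep 5" = "EQCKVZCYEQGALSPELLRRCLDNCEK",
  "VhTI-pep 6" = "EQCSVTCEQGAELPSNEERCLDNCEK")

PUBLISHED_CALC_MH <- c(
  "pepitem" = 1548.6, "VhTI-pep 1" = 3248.4, "VhTI-pep 2" = 3161.4,
  "VhTI-pep 3" = 3219.4, "VhTI-pep 4" = 3177.4, "VhTI-pep 5" = 3177.4,
  "VhTI-pep 6" = 2951.2, "VhTI variant" = 3258.5)

published_specs <- function() {
  c(lapply(PUBLISHED_SEQS, PeptideSpec, n_term = "acetyl", c_term = "amide",
           n_disulfides = 2L),
    list("pepitem" = pepitemSpec(), "VhTI variant" = vhtiScaffold()))
}
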