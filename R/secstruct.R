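#' Secondary-structure assignment parameters
#'
#' Distance windows (in Angstrom) for the C-alpha-only assignment used by
#' [assignSecStruct()]. A 5-residue window starting at residue i is
#' helix-compatible when d(i,i+2), d(i,i+3) and d(i,i+4) fall inside the
#' helix ranges; a 3-residue window is strand-compatible when d(i,i+2) falls
#' in the extended range with near-straight local geometry.
#'
#' @param helix_d2,helix_d3,helix_d4 helix ranges for d(i,i+2), d(i,i+3),
#'   d(i,i+4).
#' @param ext_d2 extended-structure range for d(i,i+2).
#' @param ext_angle_min minimum C-alpha pseudo-bond angle (degrees) for the
#'   extended label (near-straight geometry).
#' @param vote minimum number of passing helix windows covering a residue for
#'   it to seed a helix (runs then extend over residues covered by at least
#'   one passing window).
#' @param min_helix minimum helix run length; shorter runs are demoted to
#'   coil.
#' @return Named list of parameters.
#' @export
secstructParams <- function(helix_d2 = c(5.0, 6.0), helix_d3 = c(4.8, 5.8),
                            helix_d4 = c(5.8, 7.0), ext_d2 = c(6.6, 7.4),
                            ext_angle_min = 120, vote = 3L,
                            min_helix = 4L) {
  list(helix_d2 = helix_d2, helix_d3 = helix_d3, helix_d4 = helix_d4,
       ext_d2 = ext_d2, ext_angle_min = ext_angle_min,
       vote = as.integer(vote), min_helix = as.integer(min_helix))
}

.ca_angle <- function(p, q, r) {
  u <- p - q; v <- r - q
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Assign per-residue secondary structure from C-alpha geometry
#'
#' P-SEA-style assignment using only C-alpha distances, so that
#' helix-loop-helix motifs can be located in models lacking full backbones.
#' Five-residue windows are tested against canonical helix distance ranges;
#' a residue seeds a helix when at least `vote` of the windows covering it
#' pass, and helix runs extend outward over residues covered by at least one
#' passing window (window support necessarily thins at helix termini, so
#' seeding alone would systematically clip helix ends). Residues in
#' near-straight stretches with extended d(i,i+2) spacing are labeled E;
#' everything else is coil. Helix runs shorter than `min_helix` are demoted
#' to coil.
#'
#' @param s a \linkS4class{PolymerStructure}.
#' @param chain chain identifier.
#' @param params see [secstructParams()].
#' @return A \linkS4class{SecStructAssignment}.
#' @examples
#' fx <- buildHLH(hlhRecipe(helix1 = 10, loop = 5, helix2 = 10))
#' assignSecStruct(fx$structure, "A")
#' @export
assignSecStruct <- function(s, chain, params = secstructParams()) {
  ca <- caCoords(s, chain)
  n <- nrow(ca)
  if (n < 5L) stop("need at least 5 residues with C-alpha (have ", n, ")")
  d <- function(i, j) sqrt(rowSums((ca[i, , drop = FALSE] -
                                    ca[j, , drop = FALSE])^2))
  in_rng <- function(x, r) x >= r[1] & x <= r[2]

  # helix windows: window j covers residues j..j+4
  jmax <- n - 4L
  j <- seq_len(jmax)
  win_pass <- in_rng(d(j, j + 2L), params$helix_d2) &
              in_rng(d(j, j + 3L), params$helix_d3) &
              in_rng(d(j, j + 4L), params$helix_d4)

  covered <- integer(n)
  for (jj in which(win_pass)) {
    idx <- jj:(jj + 4L)
    covered[idx] <- covered[idx] + 1L
  }
  core <- covered >= params$vote
  any_cov <- covered >= 1L
  helix <- core
  # extend seeded runs over residues with any window support
  repeat {
    grow <- (!helix) & any_cov &
      (c(FALSE, helix[-n]) | c(helix[-1], FALSE))
    if (!any(grow)) break
    helix <- helix | grow
  }

  labels <- rep("C", n)
  labels[helix] <- "H"

  # extended: d(i,i+2) in range and near-straight pseudo-bond angle at i+1
  kmax <- n - 2L
  k <- seq_len(kmax)
  ang <- vapply(k, function(i) .ca_angle(ca[i, ], ca[i + 1L, ],
                                         ca[i + 2L, ]), numeric(1))
  e_win <- in_rng(d(k, k + 2L), params$ext_d2) & ang >= params$ext_angle_min
  e_res <- logical(n)
  for (kk in which(e_win)) e_res[kk:(kk + 2L)] <- TRUE
  labels[e_res & !helix] <- "E"

  # demote short helix runs
  r <- rle(labels)
  r$values[r$values == "H" & r$lengths < params$min_helix] <- "C"
  labels <- inverse.rle(r)

  new("SecStructAssignment", labels = labels, chain = chain,
      parameters = params)
}
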