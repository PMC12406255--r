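# Residue (i.e. dehydrated amino acid) masses, Dalton.
# Monoisotopic values from the standard amino-acid residue table
# (CODATA/IUPAC isotope masses); averages from IUPAC standard atomic
# weights. Z = norleucine, elemental composition C6H11NO -- identical to
# leucine/isoleucine, hence identical residue mass.
.MONO_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931, Z = 113.08406)

.AVG_RESIDUE <- c(
  G = 57.0513, A = 71.0779, S = 87.0773, P = 97.1152, V = 99.1311,
  T = 101.1039, C = 103.1429, L = 113.1576, I = 113.1576, N = 114.1026,
  D = 115.0874, Q = 128.1292, K = 128.1723, E = 129.1140, M = 131.1961,
  H = 137.1393, F = 147.1739, R = 156.1857, Y = 163.1733, W = 186.2099,
  Z = 113.1576)

# Modification and terminus masses, Dalton.
.MASS_CONST <- list(
  water_mono = 18.010565,  water_avg = 18.0153,
  acetyl_mono = 42.010565, acetyl_avg = 42.0367,   # +C2H2O
  amide_mono = -0.984016,  amide_avg = -0.9847,    # OH -> NH2
  ss_mono = -2.015650,     ss_avg = -2.0159,       # -2H per disulfide
  proton = 1.00728,        h_avg = 1.00794)

#' Compute the mass of a modified peptide
#'
#' Neutral mass = sum of residue masses + H2O, plus the terminal
#' modifications (N-acetyl +42.01057 Da mono; C-amide -0.98402 Da mono) and
#' -2.01565 Da per disulfide bond (loss of two hydrogens on oxidation).
#' Norleucine (`Z`) uses the leucine/isoleucine elemental composition
#' (C6H11NO residue). Both monoisotopic and average masses are reported,
#' together with the singly protonated \eqn{[M+H]^+} values.
#'
#' @param p a \linkS4class{PeptideSpec}.
#' @return A \linkS4class{MassResult}.
#' @examples
#' computeMass(PeptideSpec("G"))  # glycine: C2H5NO2, mono 75.03203
#' @export
computeMass <- function(p) {
  stopifnot(is(p, "PeptideSpec"))
  ch <- strsplit(p@sequence, "")[[1]]
  unknown <- setdiff(ch, names(.MONO_RESIDUE))
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unique(unknown), collapse = " "))
  k <- .MASS_CONST
  delta <- c(water = k$water_mono)
  mono <- sum(.MONO_RESIDUE[ch]) + k$water_mono
  avg <- sum(.AVG_RESIDUE[ch]) + k$water_avg
  if (p@nTerm == "acetyl") {
    mono <- mono + k$acetyl_mono; avg <- avg + k$acetyl_avg
    delta <- c(delta, acetyl = k$acetyl_mono)
  }
  if (p@cTerm == "amide") {
    mono <- mono + k$amide_mono; avg <- avg + k$amide_avg
    delta <- c(delta, amide = k$amide_mono)
  }
  if (p@nDisulfides > 0L) {
    mono <- mono + p@nDisulfides * k$ss_mono
    avg <- avg + p@nDisulfides * k$ss_avg
    delta <- c(delta, disulfide = p@nDisulfides * k$ss_mono)
  }
  new("MassResult", monoNeutral = mono, avgNeutral = avg,
      monoMH = mono + k$proton, avgMH = avg + k$h_avg,
      compositionDelta = delta)
}

#' Monoisotopic mass difference between two peptides
#'
#' @param p,q \linkS4class{PeptideSpec}s.
#' @return `computeMass(p)@monoNeutral - computeMass(q)@monoNeutral`, Da.
#' @export
massDelta <- function(p, q) {
  computeMass(p)@monoNeutral - computeMass(q)@monoNeutral
}

#' Mass table for a set of designs
#'
#' @param designs list of \linkS4class{GraftDesign} or
#'   \linkS4class{PeptideSpec}.
#' @return data.frame: name, mono M, mono \eqn{[M+H]^+}, avg M, avg
#'   \eqn{[M+H]^+}.
#' @export
massTable <- function(designs) {
  specs <- lapply(designs, function(d)
    if (is(d, "GraftDesign")) d@chimera else d)
  nm <- names(designs)
  if (is.null(nm)) nm <- paste0("peptide_", seq_along(designs))
  do.call(rbind, lapply(seq_along(specs), function(i) {
    m <- computeMass(specs[[i]])
    data.frame(name = nm[i], mono_M = m@monoNeutral, mono_MH = m@monoMH,
               avg_M = m@avgNeutral, avg_MH = m@avgMH,
               stringsAsFactors = FALSE)
  }))
}
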