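#' @import methods
NULL

#' Parsed polymer structure
#'
#' Container for the polymer content of a PDB/mmCIF entry: one row per atom,
#' grouped into residues and chains. Only polymer residues carrying at least a
#' C-alpha atom are kept by [readStructure()]; waters and ligands are dropped.
#' Residues carry both the author residue number (`resno`, the numbering
#' printed in the source file) and a gap-free sequential `label_id` (1..n per
#' chain) used for all internal indexing.
#'
#' @slot id entry identifier (e.g. a PDB code or file stem).
#' @slot atoms data.frame with columns `chain`, `resno`, `insert`, `label_id`,
#'   `resid` (3-letter code), `elety` (atom name), `element`, `x`, `y`, `z`,
#'   `o` (occupancy), `alt` (altloc character, `""` if none).
#' @slot metadata free-form named list.
#' @exportClass PolymerStructure
setClass("PolymerStructure",
  representation(id = "character", atoms = "data.frame", metadata = "list"),
  prototype(id = NA_character_, metadata = list()))

setValidity("PolymerStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "insert", "label_id", "resid", "elety",
            "element", "x", "y", "z", "o", "alt")
  if (!all(need %in% names(a)))
    return(paste("atoms missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) == 0L) return("structure has no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite atom coordinates")
  if (any(a$o < 0 | a$o > 1, na.rm = TRUE))
    return("occupancy outside [0, 1]")
  for (ch in unique(a$chain)) {
    lid <- unique(a$label_id[a$chain == ch])
    if (!identical(sort(lid), seq_along(lid)))
      return(sprintf("chain %s: label_id is not a 1..n index", ch))
  }
  TRUE
})

#' Per-residue secondary-structure labels
#'
#' One label per residue over the alphabet H (helix), E (extended), C (coil),
#' assigned from C-alpha geometry by [assignSecStruct()].
#'
#' @slot labels character vector of single letters in `{H, E, C}`.
#' @slot chain chain identifier the labels refer to.
#' @slot parameters list of the distance thresholds used.
#' @exportClass SecStructAssignment
setClass("SecStructAssignment",
  representation(labels = "character", chain = "character",
                 parameters = "list"))

setValidity("SecStructAssignment", function(object) {
  if (!all(object@labels %in% c("H", "E", "C")))
    return("labels must be in {H, E, C}")
  TRUE
})

#' Helix-loop-helix motif
#'
#' Two helical spans joined by a loop, on one chain. Spans are inclusive
#' `(start, end)` pairs in sequential `label_id` numbering.
#'
#' @slot chain chain identifier.
#' @slot helix1,loop,helix2 integer length-2 spans, contiguous and ordered.
#' @slot source identifier of the parent structure.
#' @exportClass HLHMotif
setClass("HLHMotif",
  representation(chain = "character", helix1 = "integer", loop = "integer",
                 helix2 = "integer", source = "character"))

setValidity("HLHMotif", function(object) {
  h1 <- object@helix1; lp <- object@loop; h2 <- object@helix2
  if (length(h1) != 2L || length(lp) != 2L || length(h2) != 2L)
    return("spans must be length-2 (start, end)")
  if (!(h1[2] + 1L == lp[1] && lp[2] + 1L == h2[1]))
    return("spans must be contiguous: helix1 < loop < helix2")
  if (diff(h1) + 1L < 4L || diff(h2) + 1L < 4L)
    return("helices must be at least 4 residues")
  if (diff(lp) + 1L < 1L) return("loop must be at least 1 residue")
  TRUE
})

#' Disulfide connectivity pattern
#'
#' Cysteine pairing detected from S-gamma (fallback C-beta) distances, with
#' the conventional Roman-numeral connectivity string in which cysteines are
#' numbered I, II, ... by sequence position.
#'
#' @slot pairs integer matrix with columns `i`, `j` (cysteine ordinals,
#'   `i < j`), zero rows when no bond is found.
#' @slot roman canonical connectivity string, e.g. `"I-IV, II-III"`
#'   (en-dashes in the actual string); `""` when there are no pairs.
#' @exportClass DisulfidePattern
setClass("DisulfidePattern",
  representation(pairs = "matrix", roman = "character"))

setValidity("DisulfidePattern", function(object) {
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must have two columns")
  if (nrow(p)) {
    if (any(p[, 1] >= p[, 2])) return("pairs must satisfy i < j")
    if (anyDuplicated(as.vector(p))) return("a cysteine may appear in at most one pair")
  }
  TRUE
})

#' Scaffold library candidate
#'
#' A chain considered for scaffold matching, with the attributes the curation
#' filter operates on (length and cysteine count) plus any detected motif and
#' disulfide pattern.
#'
#' @slot source structure identifier.
#' @slot chain chain identifier.
#' @slot sequence 1-letter chain sequence.
#' @slot length residue count.
#' @slot nCys number of cysteines.
#' @slot motif list of [HLHMotif-class] (possibly empty).
#' @slot disulfides [DisulfidePattern-class].
#' @exportClass ScaffoldCandidate
setClass("ScaffoldCandidate",
  representation(source = "character", chain = "character",
                 sequence = "character", length = "integer",
                 nCys = "integer", motif = "list",
                 disulfides = "DisulfidePattern"))

setValidity("ScaffoldCandidate", function(object) {
  if (object@length < 1L) return("length must be >= 1")
  if (object@nCys < 0L) return("nCys must be >= 0")
  if (nchar(object@sequence) != object@length)
    return("sequence length disagrees with length slot")
  TRUE
})

#' Rigid-body superposition result
#'
#' Output of [kabsch()], [frameworkAlign()] or [ceStyleAlign()]: the optimal
#' proper rotation and translation mapping the first (mobile) coordinate set
#' onto the second (fixed), the residue correspondence used, and the RMSD
#' after transformation.
#'
#' @slot rotation 3x3 proper orthogonal matrix (det +1).
#' @slot translation length-3 numeric, Angstrom.
#' @slot rmsd root-mean-square deviation after superposition, Angstrom
#'   (`NA` when no alignment was found).
#' @slot correspondence integer matrix, columns `query`/`candidate` residue
#'   `label_id`s, strictly increasing in both columns.
#' @slot mode one of `"all_atom_ca"`, `"framework"`, `"ce_style"`.
#' @slot details list: may carry `loop_rmsd`, `ill_conditioned`, `offsets`,
#'   `aligned`, `reason`.
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", correspondence = "matrix",
                 mode = "character", details = "list"),
  prototype(details = list()))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (abs(det(R) - 1) > 1e-9) return("rotation must be proper (det +1)")
  if (!is.na(object@rmsd) && object@rmsd < 0) return("rmsd must be >= 0")
  cr <- object@correspondence
  if (nrow(cr) > 1L &&
      (any(diff(cr[, 1]) <= 0) || any(diff(cr[, 2]) <= 0)))
    return("correspondence must be strictly increasing in both columns")
  if (!object@mode %in% c("all_atom_ca", "framework", "ce_style"))
    return("unknown mode")
  TRUE
})

#' Modified peptide specification
#'
#' A peptide at the sequence level: 1-letter residues (Z = norleucine, the
#' methionine bioisostere used in synthesized scaffolds), terminal
#' modifications and the number of disulfide bonds formed on folding.
#'
#' @slot sequence uppercase 1-letter string; alphabet = 20 standard residues
#'   plus Z (norleucine).
#' @slot nTerm `"free"` or `"acetyl"`.
#' @slot cTerm `"free"` or `"amide"`.
#' @slot nDisulfides number of disulfide bonds, at most `floor(#C / 2)`.
#' @exportClass PeptideSpec
setClass("PeptideSpec",
  representation(sequence = "character", nTerm = "character",
                 cTerm = "character", nDisulfides = "integer"))

.PEP_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "Z")

setValidity("PeptideSpec", function(object) {
  s <- object@sequence
  if (!nzchar(s)) return("sequence must be non-empty")
  ch <- strsplit(s, "")[[1]]
  bad <- setdiff(ch, .PEP_ALPHABET)
  if (length(bad))
    return(paste("invalid residue code(s):", paste(unique(bad), collapse = " ")))
  if (!object@nTerm %in% c("free", "acetyl")) return("nTerm must be free|acetyl")
  if (!object@cTerm %in% c("free", "amide")) return("cTerm must be free|amide")
  if (object@nDisulfides < 0L) return("nDisulfides must be >= 0")
  if (object@nDisulfides > sum(ch == "C") %/% 2L)
    return("nDisulfides exceeds floor(#Cys / 2)")
  TRUE
})

#' Grafted chimera design
#'
#' A chimera built by splicing an insert into a scaffold span. The chimera
#' sequence is derived, never set directly:
#' `scaffold[1:(start-1)] + insert + scaffold[(end+1):n]`; it inherits the
#' scaffold's terminal modifications and disulfide count.
#'
#' @slot name design identifier.
#' @slot scaffold [PeptideSpec-class] the splice starts from.
#' @slot span integer `(start, end)`, 1-based inclusive on the scaffold.
#' @slot insert replacement sequence (may be `""` for a deletion).
#' @slot chimera derived [PeptideSpec-class].
#' @slot provenance character vector of free-text provenance records.
#' @exportClass GraftDesign
setClass("GraftDesign",
  representation(name = "character", scaffold = "PeptideSpec",
                 span = "integer", insert = "character",
                 chimera = "PeptideSpec", provenance = "character"))

setValidity("GraftDesign", function(object) {
  sp <- object@span
  n <- nchar(object@scaffold@sequence)
  if (length(sp) != 2L || sp[1] < 1L || sp[2] > n || sp[1] > sp[2])
    return("span must satisfy 1 <= start <= end <= scaffold length")
  expect <- paste0(substr(object@scaffold@sequence, 1L, sp[1] - 1L),
                   object@insert,
                   substr(object@scaffold@sequence, sp[2] + 1L, n))
  if (!identical(object@chimera@sequence, expect))
    return("chimera sequence is not the splice of scaffold and insert")
  TRUE
})

#' Peptide mass computation result
#'
#' Monoisotopic and average neutral masses plus singly protonated
#' \eqn{[M+H]^+} masses of a modified peptide, in Dalton.
#'
#' @slot monoNeutral,avgNeutral neutral masses, Da.
#' @slot monoMH,avgMH \eqn{[M+H]^+} masses, Da.
#' @slot compositionDelta named numeric of applied modification masses
#'   (monoisotopic), Da.
#' @exportClass MassResult
setClass("MassResult",
  representation(monoNeutral = "numeric", avgNeutral = "numeric",
                 monoMH = "numeric", avgMH = "numeric",
                 compositionDelta = "numeric"))

setValidity("MassResult", function(object) {
  if (any(c(object@monoNeutral, object@avgNeutral,
            object@monoMH, object@avgMH) <= 0))
    return("masses must be positive")
  TRUE
})

#' Per-column conservation profile
#'
#' Column-wise residue frequencies, Shannon entropy and information content
#' of a pre-aligned, equal-length sequence set (the computation behind a
#' sequence logo). Gaps are tallied separately and excluded from entropy.
#'
#' @slot nSequences number of sequences profiled.
#' @slot freq 21 x L matrix (20 residues + `-`), columns sum to 1.
#' @slot entropy per-column Shannon entropy, bits (non-gap residues,
#'   renormalized).
#' @slot ic per-column information content, bits: `log2(20) - entropy`,
#'   clipped at 0 (minus a small-sample correction when requested).
#' @slot consensus per-column consensus residue (ties alphabetical; `NA` for
#'   all-gap columns).
#' @slot gapFraction per-column gap fraction.
#' @slot correction logical; whether the small-sample correction was applied.
#' @exportClass ConservationProfile
setClass("ConservationProfile",
  representation(nSequences = "integer", freq = "matrix",
                 entropy = "numeric", ic = "numeric",
                 consensus = "character", gapFraction = "numeric",
                 correction = "logical"))

setValidity("ConservationProfile", function(object) {
  if (nrow(object@freq) != 21L) return("freq must have 21 rows (20 aa + gap)")
  cs <- colSums(object@freq)
  if (any(abs(cs - 1) > 1e-9)) return("column frequencies must sum to 1")
  if (any(object@entropy < -1e-12 | object@entropy > log2(21) + 1e-12,
          na.rm = TRUE))
    return("entropy outside [0, log2(21)]")
  if (any(object@ic < -1e-12, na.rm = TRUE)) return("ic must be >= 0")
  TRUE
})

#' Constrained three-parameter dose-response fit
#'
#' Least-squares fit of
#' \eqn{Y = bottom + (top - bottom) / (1 + 10^{\log_{10} c - \log_{10} EC_{50}})}
#' with the top constrained to 100 (% of untreated control) and the Hill
#' slope fixed to 1.
#'
#' @slot ec50 half-maximal concentration, same units as the input.
#' @slot bottom lower plateau, % of control.
#' @slot top fixed upper plateau (100).
#' @slot slope fixed Hill slope (1).
#' @slot rss residual sum of squares.
#' @slot converged logical.
#' @slot reason diagnostic string when not converged.
#' @exportClass DoseResponseFit
setClass("DoseResponseFit",
  representation(ec50 = "numeric", bottom = "numeric", top = "numeric",
                 slope = "numeric", rss = "numeric", converged = "logical",
                 reason = "character"))

setValidity("DoseResponseFit", function(object) {
  if (object@converged) {
    if (!is.na(object@ec50) && object@ec50 <= 0) return("ec50 must be > 0")
    if (object@bottom > object@top + 1e-9) return("bottom must be <= top")
  }
  TRUE
})

#' One-phase exponential decay fit
#'
#' Least-squares fit of \eqn{Y = (y_0 - plateau) e^{-kt} + plateau} to a
#' remaining-fraction time series (serum stability), reporting the half-life
#' \eqn{t_{1/2} = \ln 2 / k}. Non-decaying series are flagged not converged
#' and carry a censored label (e.g. `">48"`) when the series stays high.
#'
#' @slot k decay rate, 1/h.
#' @slot y0 fitted value at t = 0, %.
#' @slot plateau asymptote, %, bounded in [0, 100].
#' @slot halfLife `log(2)/k`, h.
#' @slot rss residual sum of squares.
#' @slot converged logical.
#' @slot reason diagnostic string when not converged.
#' @slot censorLabel e.g. `">48"` for stable peptides, else `""`.
#' @exportClass DecayFit
setClass("DecayFit",
  representation(k = "numeric", y0 = "numeric", plateau = "numeric",
                 halfLife = "numeric", rss = "numeric",
                 converged = "logical", reason = "character",
                 censorLabel = "character"))

setValidity("DecayFit", function(object) {
  if (object@converged && (is.na(object@k) || object@k <= 0))
    return("k must be > 0 when converged")
  if (object@converged && object@halfLife <= 0)
    return("half-life must be > 0 when converged")
  TRUE
})
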