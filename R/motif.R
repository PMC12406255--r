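#' Extract helix-loop-helix motifs from a labeled chain
#'
#' Every consecutive pair of maximal helix runs separated by a non-helix gap
#' of 1 to `max_loop` residues yields one motif; the gap residues form the
#' loop. Motifs are returned N- to C-terminal.
#'
#' @param labels a \linkS4class{SecStructAssignment}.
#' @param source identifier of the parent structure (recorded in the motif).
#' @param max_loop maximum loop length; beyond this two helices are no
#'   longer considered a single turn.
#' @param min_helix minimum helix run length to participate in a motif.
#' @return List of \linkS4class{HLHMotif} (possibly empty).
#' @export
extractHLHMotifs <- function(labels, source = NA_character_, max_loop = 12L,
                             min_helix = 4L) {
  stopifnot(is(labels, "SecStructAssignment"))
  lab <- labels@labels
  r <- rle(lab == "H")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hruns <- which(r$values & r$lengths >= min_helix)
  out <- list()
  if (length(hruns) >= 2L) {
    for (k in seq_len(length(hruns) - 1L)) {
      i <- hruns[k]; j <- hruns[k + 1L]
      # the gap must be purely non-helix (no short intervening H run)
      gap_runs <- if (j > i + 1L) (i + 1L):(j - 1L) else integer(0)
      if (any(r$values[gap_runs])) next
      gap_len <- ends[j - 1L] - ends[i]
      if (gap_len < 1L || gap_len > max_loop) next
      out[[length(out) + 1L]] <- new("HLHMotif",
        chain = labels@chain,
        helix1 = c(starts[i], ends[i]),
        loop = c(ends[i] + 1L, ends[i] + gap_len),
        helix2 = c(starts[j], ends[j]),
        source = as.character(source))
    }
  }
  out
}

.roman_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return("")
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  paste(sprintf("%s–%s", as.character(utils::as.roman(pairs[, 1])),
                as.character(utils::as.roman(pairs[, 2]))),
        collapse = ", ")
}

#' Detect disulfide bonds and their Roman-numeral connectivity
#'
#' Cysteine pairs are considered bonded when their S-gamma atoms lie within
#' `sg_max` Angstrom; when either S-gamma is missing from the model the
#' C-beta--C-beta distance is used with threshold `cb_max`. Pairing is
#' greedy nearest-first. Cysteines are numbered I, II, ... by sequence
#' position and the connectivity string lists pairs sorted by first member
#' (e.g. a two-disulfide helix staple reads "I--IV, II--III").
#'
#' @param s a \linkS4class{PolymerStructure}.
#' @param chain chain identifier.
#' @param sg_max S-gamma distance threshold, Angstrom (canonical bond length
#'   2.05 plus slack).
#' @param cb_max C-beta fallback threshold, Angstrom.
#' @return A \linkS4class{DisulfidePattern}.
#' @export
detectDisulfides <- function(s, chain, sg_max = 2.3, cb_max = 4.5) {
  rt <- residueTable(s, chain)
  cys <- rt$label_id[rt$one == "C"]
  empty <- new("DisulfidePattern",
               pairs = matrix(integer(0), ncol = 2,
                              dimnames = list(NULL, c("i", "j"))),
               roman = "")
  if (length(cys) < 2L) return(empty)
  a <- .chain_atoms(s, chain)
  atom_xyz <- function(lid, name) {
    row <- a[a$label_id == lid & a$elety == name, , drop = FALSE]
    if (nrow(row) == 0L) return(NULL)
    as.numeric(row[1L, c("x", "y", "z")])
  }
  k <- length(cys)
  cand <- NULL
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    sgi <- atom_xyz(cys[i], "SG"); sgj <- atom_xyz(cys[j], "SG")
    if (!is.null(sgi) && !is.null(sgj)) {
      dd <- sqrt(sum((sgi - sgj)^2)); thr <- sg_max
    } else {
      cbi <- atom_xyz(cys[i], "CB"); cbj <- atom_xyz(cys[j], "CB")
      if (is.null(cbi) || is.null(cbj)) next
      dd <- sqrt(sum((cbi - cbj)^2)); thr <- cb_max
    }
    if (dd <= thr)
      cand <- rbind(cand, c(i = i, j = j, d = dd))
  }
  if (is.null(cand)) return(empty)
  cand <- cand[order(cand[, "d"]), , drop = FALSE]
  used <- logical(k)
  pairs <- NULL
  conflict <- FALSE
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, "i"]; j <- cand[r, "j"]
    if (used[i] || used[j]) { conflict <- TRUE; next }
    used[i] <- used[j] <- TRUE
    pairs <- rbind(pairs, c(i, j))
  }
  if (conflict)
    warning("cysteine within bonding distance of an already paired ",
            "partner; kept nearest-first assignment")
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  new("DisulfidePattern", pairs = pairs, roman = .roman_pairs(pairs))
}

#' Build a scaffold candidate from a structure chain
#'
#' Convenience constructor computing the attributes the curation filter and
#' ranking operate on: sequence, length, cysteine count, detected
#' helix-loop-helix motifs and disulfide pattern.
#'
#' @param s a \linkS4class{PolymerStructure}.
#' @param chain chain identifier (default: first chain).
#' @param params secondary-structure parameters, see [secstructParams()].
#' @return A \linkS4class{ScaffoldCandidate}.
#' @export
scaffoldCandidate <- function(s, chain = chainIds(s)[1],
                              params = secstructParams()) {
  seq <- chainSequence(s, chain)
  n <- nchar(seq)
  motifs <- if (n >= 5L) {
    extractHLHMotifs(assignSecStruct(s, chain, params), source = s@id)
  } else list()
  new("ScaffoldCandidate", source = s@id, chain = chain, sequence = seq,
      length = n, nCys = sum(strsplit(seq, "")[[1]] == "C"),
      motif = motifs, disulfides = detectDisulfides(s, chain))
}

#' Scaffold curation filter
#'
#' Passes candidates that are 10 to 50 residues long (both bounds inclusive)
#' and contain at least `min_cys` cysteines; failures carry machine-readable
#' reason codes (`too_short`, `too_long`, `too_few_cys`). The verdict is a
#' pure function of (length, cysteine count).
#'
#' @param x a \linkS4class{ScaffoldCandidate}, or an integer length.
#' @param n_cys cysteine count (only when `x` is a length).
#' @param min_len,max_len inclusive length bounds.
#' @param min_cys minimum cysteine count.
#' @return List with `pass` (logical) and `reasons` (character vector,
#'   empty on pass).
#' @export
scaffoldFilter <- function(x, n_cys = NULL, min_len = 10L, max_len = 50L,
                           min_cys = 2L) {
  if (is(x, "ScaffoldCandidate")) {
    len <- x@length; nc <- x@nCys
  } else {
    stopifnot(is.numeric(x), !is.null(n_cys))
    len <- as.integer(x); nc <- as.integer(n_cys)
  }
  reasons <- character(0)
  if (len < min_len) reasons <- c(reasons, "too_short")
  if (len > max_len) reasons <- c(reasons, "too_long")
  if (nc < min_cys) reasons <- c(reasons, "too_few_cys")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Remove redundant candidates
#'
#' Keeps one candidate per identical chain sequence; among duplicates the
#' lexicographically smallest source id survives. Output order follows the
#' first appearance of each sequence in the input.
#'
#' @param cs list of \linkS4class{ScaffoldCandidate}.
#' @return Deduplicated list.
#' @export
dedupeCandidates <- function(cs) {
  if (length(cs) == 0L) return(cs)
  seqs <- vapply(cs, function(c) c@sequence, character(1))
  srcs <- vapply(cs, function(c) c@source, character(1))
  keep <- integer(0)
  for (sq in unique(seqs)) {
    idx <- which(seqs == sq)
    keep <- c(keep, idx[order(srcs[idx])][1L])
  }
  cs[sort(keep)]
}
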