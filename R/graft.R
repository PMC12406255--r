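#' Create a modified peptide specification
#'
#' @param sequence uppercase 1-letter sequence; `Z` denotes norleucine.
#' @param n_term `"free"` or `"acetyl"`.
#' @param c_term `"free"` or `"amide"`.
#' @param n_disulfides number of disulfide bonds formed on folding.
#' @return A \linkS4class{PeptideSpec}.
#' @examples
#' PeptideSpec("SVTEQGAELSNEER")                 # pepitem
#' @export
PeptideSpec <- function(sequence, n_term = c("free", "acetyl"),
                        c_term = c("free", "amide"), n_disulfides = 0L) {
  new("PeptideSpec", sequence = toupper(sequence),
      nTerm = match.arg(n_term), cTerm = match.arg(c_term),
      nDisulfides = as.integer(n_disulfides))
}

#' Splice an insert into a scaffold span
#'
#' Builds a chimera by replacing the 1-based inclusive span
#' `(start, end)` of the scaffold sequence with `insert` (which may be empty,
#' i.e. a pure deletion). The chimera inherits the scaffold's terminal
#' modifications and disulfide count; a warning is raised when the insert
#' introduces cysteines, since that changes the disulfide bookkeeping.
#'
#' @param scaffold a \linkS4class{PeptideSpec}.
#' @param span integer `(start, end)` on the scaffold sequence.
#' @param insert replacement sequence (possibly `""`).
#' @param name design identifier.
#' @param provenance free-text provenance.
#' @return A \linkS4class{GraftDesign}.
#' @examples
#' d <- buildChimera(vhtiScaffold(), c(9, 14), "AQGAEL", "VhTI-pep 2")
#' peptideSequence(d)  # "EQCKVZCYAQGAELPELLRRCLDNCEK"
#' @export
buildChimera <- function(scaffold, span, insert, name = "chimera",
                         provenance = character(0)) {
  stopifnot(is(scaffold, "PeptideSpec"))
  span <- as.integer(span)
  n <- nchar(scaffold@sequence)
  if (length(span) != 2L || span[1] < 1L || span[2] > n ||
      span[1] > span[2])
    stop("span out of range: need 1 <= start <= end <= ", n)
  insert <- toupper(insert)
  if (nzchar(insert)) {
    bad <- setdiff(strsplit(insert, "")[[1]], .PEP_ALPHABET)
    if (length(bad))
      stop("invalid residue code(s) in insert: ",
           paste(unique(bad), collapse = " "))
  }
  removed <- substr(scaffold@sequence, span[1], span[2])
  if (grepl("C", insert, fixed = TRUE) || grepl("C", removed, fixed = TRUE))
    warning("splice changes cysteine content; verify disulfide count")
  chim_seq <- paste0(substr(scaffold@sequence, 1L, span[1] - 1L), insert,
                     substr(scaffold@sequence, span[2] + 1L, n))
  chimera <- new("PeptideSpec", sequence = chim_seq,
                 nTerm = scaffold@nTerm, cTerm = scaffold@cTerm,
                 nDisulfides = scaffold@nDisulfides)
  if (!length(provenance))
    provenance <- sprintf("splice %d-%d ('%s') <- '%s'", span[1], span[2],
                          removed, insert)
  new("GraftDesign", name = name, scaffold = scaffold, span = span,
      insert = insert, chimera = chimera, provenance = provenance)
}

#' Enumerate grafted designs over epitope registers
#'
#' Builds one design per register, where each register is a contiguous
#' `(offset, length)` window into the epitope whose substring becomes the
#' insert for the given scaffold span. Designs are produced in deterministic
#' order (offset, then length); duplicate chimera sequences are collapsed
#' with merged provenance.
#'
#' @param scaffold a \linkS4class{PeptideSpec}.
#' @param span scaffold span to replace, `(start, end)`.
#' @param epitope epitope sequence the registers index into.
#' @param registers data.frame (or list of pairs) with columns `offset` and
#'   `length`, 1-based into the epitope.
#' @param prefix design name prefix.
#' @return List of \linkS4class{GraftDesign}.
#' @export
enumerateDesigns <- function(scaffold, span, epitope, registers,
                             prefix = "design") {
  if (is.list(registers) && !is.data.frame(registers))
    registers <- do.call(rbind.data.frame,
                         lapply(registers, function(r)
                           data.frame(offset = r[[1]], length = r[[2]])))
  if (is.null(registers) || nrow(registers) == 0L)
    stop("register list must be non-empty")
  ne <- nchar(epitope)
  if (any(registers$offset < 1L | registers$length < 1L |
          registers$offset + registers$length - 1L > ne))
    stop("register window exceeds epitope bounds (epitope length ", ne, ")")
  registers <- registers[order(registers$offset, registers$length), ,
                         drop = FALSE]
  designs <- list()
  for (r in seq_len(nrow(registers))) {
    off <- registers$offset[r]; len <- registers$length[r]
    ins <- substr(epitope, off, off + len - 1L)
    prov <- sprintf("register offset=%d length=%d ('%s')", off, len, ins)
    d <- buildChimera(scaffold, span, ins,
                      name = sprintf("%s_%02d", prefix, r),
                      provenance = prov)
    key <- d@chimera@sequence
    hit <- which(vapply(designs, function(x) x@chimera@sequence,
                        character(1)) == key)
    if (length(hit)) {
      designs[[hit]]@provenance <- c(designs[[hit]]@provenance, prov)
    } else {
      designs[[length(designs) + 1L]] <- d
    }
  }
  designs
}

#' Substitute a single residue
#'
#' @param p a \linkS4class{PeptideSpec}.
#' @param position 1-based position.
#' @param new_residue replacement 1-letter code (`Z` = norleucine).
#' @return A \linkS4class{PeptideSpec} with the substitution applied; all
#'   other fields preserved.
#' @examples
#' applySubstitution(PeptideSpec("AMAAAA"), 2, "Z")
#' @export
applySubstitution <- function(p, position, new_residue) {
  stopifnot(is(p, "PeptideSpec"))
  position <- as.integer(position)
  if (position < 1L || position > nchar(p@sequence))
    stop("position out of range: 1..", nchar(p@sequence))
  new_residue <- toupper(new_residue)
  if (nchar(new_residue) != 1L || !new_residue %in% .PEP_ALPHABET)
    stop("invalid residue code: '", new_residue, "'")
  s <- p@sequence
  substr(s, position, position) <- new_residue
  new("PeptideSpec", sequence = s, nTerm = p@nTerm, cTerm = p@cTerm,
      nDisulfides = p@nDisulfides)
}

#' Reference peptide specifications
#'
#' `vhtiScaffold()` returns the synthesized 27-residue VhTI scaffold variant
#' (residues 5--31 of the native alpha-hairpinin trypsin inhibitor, with
#' norleucine replacing the oxidation-prone methionine at position 6,
#' N-terminal acetyl, C-terminal amide, two disulfides with connectivity
#' I--IV, II--III). `pepitemSpec()` returns the unmodified 14-residue linear
#' pepitem peptide.
#'
#' @return A \linkS4class{PeptideSpec}.
#' @export
vhtiScaffold <- function() {
  PeptideSpec("EQCKVZCYAQRHSSPELLRRCLDNCEK", n_term = "acetyl",
              c_term = "amide", n_disulfides = 2L)
}

#' @rdname vhtiScaffold
#' @export
pepitemSpec <- function() PeptideSpec("SVTEQGAELSNEER")

#' Read a graft design configuration
#'
#' Parses a YAML design config listing the scaffold (sequence, terminal
#' modifications, disulfide count) and the designs, each as one or more
#' sequential splice steps (`span`, `insert`) applied to the evolving
#' sequence. Multi-span grafts (helices and loop) are plain multi-step
#' entries. The packaged config reproducing the published VhTI-pep 1--6
#' series is at `system.file("extdata", "vhti_designs.yaml",
#' package = "ScaffoldMatch")`.
#'
#' @param path YAML file path.
#' @return List of \linkS4class{GraftDesign}, named by design; the scaffold
#'   spec in `attr(, "scaffold")` and any reference peptides in
#'   `attr(, "reference")`.
#' @export
readDesignConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  sc <- cfg$scaffold
  scaffold <- PeptideSpec(sc$sequence, n_term = sc$n_term %||% "free",
                          c_term = sc$c_term %||% "free",
                          n_disulfides = sc$n_disulfides %||% 0L)
  designs <- list()
  for (d in cfg$designs) {
    cur <- scaffold
    prov <- character(0)
    last <- NULL
    for (st in d$steps) {
      last <- buildChimera(cur, unlist(st$span), st$insert, name = d$name)
      prov <- c(prov, last@provenance)
      cur <- last@chimera
    }
    # represent a multi-step graft by its final step with full provenance
    last@provenance <- prov
    designs[[d$name]] <- last
  }
  attr(designs, "scaffold") <- scaffold
  ref <- lapply(cfg$reference, PeptideSpec)
  attr(designs, "reference") <- ref
  designs
}

#' Packaged VhTI grafting designs
#'
#' Builds the packaged design series: the pepitem loop epitope and its
#' variants spliced into the loop (and, for the multi-span design, the
#' helices) of the VhTI scaffold variant, reproducing the synthesized
#' VhTI-pep 1--6 chimeras.
#'
#' @return See [readDesignConfig()].
#' @examples
#' ds <- vhtiDesigns()
#' peptideSequence(ds[["VhTI-pep 2"]])
#' @export
vhtiDesigns <- function() {
  readDesignConfig(system.file("extdata", "vhti_designs.yaml",
                               package = "ScaffoldMatch", mustWork = TRUE))
}

#' Write designs as FASTA with a modification header
#'
#' One record per design; terminal modifications and the disulfide count are
#' carried in the header as `key=value` pairs.
#'
#' @param designs list of \linkS4class{GraftDesign} or
#'   \linkS4class{PeptideSpec}.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeDesignFasta <- function(designs, path) {
  specs <- lapply(designs, function(d)
    if (is(d, "GraftDesign")) d@chimera else d)
  nm <- names(designs)
  if (is.null(nm)) nm <- vapply(designs, function(d)
    if (is(d, "GraftDesign")) d@name else "peptide", character(1))
  seqs <- vapply(specs, function(p) p@sequence, character(1))
  hdr <- vapply(seq_along(specs), function(i)
    sprintf("%s n_term=%s c_term=%s n_disulfides=%d",
            gsub("[[:space:]]+", "_", nm[i]),
            specs[[i]]@nTerm, specs[[i]]@cTerm, specs[[i]]@nDisulfides),
    character(1))
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

#' Summarize designs as a table
#'
#' @param designs list of \linkS4class{GraftDesign}.
#' @return data.frame with name, sequence, length, terminal modifications,
#'   disulfide count and provenance.
#' @export
designSummary <- function(designs) {
  do.call(rbind, lapply(seq_along(designs), function(i) {
    d <- designs[[i]]
    p <- if (is(d, "GraftDesign")) d@chimera else d
    data.frame(
      name = names(designs)[i] %||%
        (if (is(d, "GraftDesign")) d@name else "peptide"),
      sequence = p@sequence, length = nchar(p@sequence),
      n_term = p@nTerm, c_term = p@cTerm, n_disulfides = p@nDisulfides,
      provenance = if (is(d, "GraftDesign"))
        paste(d@provenance, collapse = "; ") else "",
      stringsAsFactors = FALSE)
  }))
}
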