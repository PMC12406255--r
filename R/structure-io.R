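# 3-letter -> 1-letter residue codes. NLE (norleucine) maps to 'Z' following
# the convention used for synthesized scaffold variants; anything else
# non-standard becomes 'X'.
.THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", NLE = "Z")

.ONE_TO_THREE <- c(stats::setNames(names(.THREE_TO_ONE), .THREE_TO_ONE),
                   X = "UNK")

.WATER_RESIDS <- c("HOH", "DOD", "WAT", "H2O")

.one_letter <- function(resid) {
  out <- unname(.THREE_TO_ONE[toupper(resid)])
  out[is.na(out)] <- "X"
  out
}

.guess_element <- function(elety) {
  # strip digits/primes, take the first letter; adequate for backbone and
  # side-chain heavy atoms (CA -> C, SG -> S, OXT -> O, ...)
  core <- sub("^[0-9']*", "", toupper(elety))
  substr(core, 1L, 1L)
}

#' Construct a PolymerStructure from an atom table
#'
#' Low-level constructor used by [readStructure()] and the synthetic fixture
#' generators. Fills in defaults (occupancy 1, empty altloc/insert, element
#' guessed from the atom name) and assigns the sequential per-chain
#' `label_id` in file order.
#'
#' @param id entry identifier.
#' @param atoms data.frame with at least `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`; optional `insert`, `o`, `alt`, `element`.
#' @param metadata named list.
#' @return A \linkS4class{PolymerStructure}.
#' @export
PolymerStructure <- function(id, atoms, metadata = list()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  atoms$o[is.na(atoms$o)] <- 1
  if (is.null(atoms$alt)) atoms$alt <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  if (is.null(atoms$element)) atoms$element <- .guess_element(atoms$elety)
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$label_id <- NA_integer_
  for (ch in unique(atoms$chain)) {
    sel <- atoms$chain == ch
    key <- paste(atoms$resno[sel], atoms$insert[sel], sep = "|")
    atoms$label_id[sel] <- match(key, unique(key))
  }
  cols <- c("chain", "resno", "insert", "label_id", "resid", "elety",
            "element", "x", "y", "z", "o", "alt")
  new("PolymerStructure", id = as.character(id),
      atoms = atoms[, cols, drop = FALSE], metadata = metadata)
}

#' Read a macromolecular structure file
#'
#' Parses a PDB or mmCIF file (via \pkg{bio3d}) into a uniform polymer model.
#' All polymer residues carrying at least a C-alpha atom are retained
#' (including non-standard residues such as norleucine); waters and ligands
#' are dropped. Alternate locations are resolved to the highest-occupancy
#' conformer (ties broken by file order), and each chain receives a gap-free
#' 1..n `label_id` alongside the author residue numbering.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`/`"mmcif"`.
#' @param id entry identifier; defaults to the file stem.
#' @return A \linkS4class{PolymerStructure}.
#' @examples
#' fx <- buildHLH(hlhRecipe(helix1 = 6, loop = 2, helix2 = 6))
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(fx$structure, f)
#' readStructure(f)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif", "mmcif"),
                          id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (format == "mmcif") format <- "cif"
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE, multi = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("parse error in '", path, "' (", format,
                             "): ", conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  a <- a[!(toupper(a$resid) %in% .WATER_RESIDS), , drop = FALSE]
  if (nrow(a) == 0L) stop("no polymer: '", path, "' contains no atoms")
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  a$chain[is.na(a$chain)] <- " "
  a$.ord <- seq_len(nrow(a))
  # keep residues that have a C-alpha (polymer), drop ligands
  reskey <- paste(a$chain, a$resno, a$insert, sep = "|")
  has_ca <- reskey %in% unique(reskey[a$elety == "CA"])
  a <- a[has_ca, , drop = FALSE]
  if (nrow(a) == 0L) stop("no polymer: '", path,
                          "' has no residues with a C-alpha atom")
  # altloc: highest occupancy per atom slot, ties -> first in file
  slot <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  ord <- order(slot, -a$o, a$.ord)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(slot[ord]), , drop = FALSE]
  a <- a[order(a$.ord), , drop = FALSE]
  atoms <- data.frame(
    chain = a$chain, resno = a$resno, insert = a$insert, resid = a$resid,
    elety = a$elety,
    element = if (!is.null(a$elesy) && !all(is.na(a$elesy)))
      ifelse(is.na(a$elesy) | a$elesy == "", .guess_element(a$elety), a$elesy)
    else .guess_element(a$elety),
    x = a$x, y = a$y, z = a$z, o = pmin(pmax(a$o, 0), 1), alt = a$alt,
    stringsAsFactors = FALSE)
  PolymerStructure(id, atoms, metadata = list(path = path, format = format))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("chainIds", "PolymerStructure", function(x) unique(x@atoms$chain))

.chain_atoms <- function(x, chain) {
  if (!chain %in% x@atoms$chain)
    stop("chain '", chain, "' not found (have: ",
         paste(chainIds(x), collapse = ", "), ")")
  x@atoms[x@atoms$chain == chain, , drop = FALSE]
}

setMethod("residueTable", "PolymerStructure", function(x, chain = NULL) {
  a <- if (is.null(chain)) x@atoms else .chain_atoms(x, chain)
  first <- !duplicated(paste(a$chain, a$label_id, sep = "|"))
  rt <- a[first, c("chain", "resno", "insert", "label_id", "resid")]
  rt$one <- .one_letter(rt$resid)
  rownames(rt) <- NULL
  rt
})

#' Chain sequence in 1-letter code
#'
#' One character per residue in `label_id` order. Norleucine (NLE) is
#' reported as `Z`; other non-standard residues as `X`.
#'
#' @param x a \linkS4class{PolymerStructure}.
#' @param chain chain identifier.
#' @param ... unused.
#' @return Single character string.
#' @export
#' @rdname chainSequence
setMethod("chainSequence", "PolymerStructure", function(x, chain, ...) {
  rt <- residueTable(x, chain)
  if (nrow(rt) == 0L) stop("empty selection for chain '", chain, "'")
  paste(rt$one, collapse = "")
})

setMethod("caCoords", "PolymerStructure",
  function(x, chain, label_ids = NULL) {
    a <- .chain_atoms(x, chain)
    a <- a[a$elety == "CA", , drop = FALSE]
    if (!is.null(label_ids)) {
      a <- a[match(label_ids, a$label_id), , drop = FALSE]
      if (anyNA(a$label_id))
        stop("missing C-alpha for requested residues in chain ", chain)
    }
    m <- as.matrix(a[, c("x", "y", "z")])
    rownames(m) <- a$label_id
    m
  })

#' Locate a subsequence
#'
#' Finds the first occurrence of `query` inside a parent sequence. On a plain
#' string the 1-based start position is returned (`NA_integer_` when absent
#' -- absence is a result, not an error). On a \linkS4class{PolymerStructure}
#' the match is reported in both sequential `label_id` and author numbering
#' of the parsed chain.
#'
#' @param parent parent sequence string, or a \linkS4class{PolymerStructure}.
#' @param query subsequence to find (1-letter code).
#' @param chain chain identifier (structure method only).
#' @return Integer start position (character method), or a list with
#'   `found`, `label_start`, `label_end`, `auth_start`, `auth_end`.
#' @examples
#' findSubsequence("ABCDE", "CD")  # 3
#' @export
setGeneric("findSubsequence",
           function(parent, query, chain) standardGeneric("findSubsequence"))

#' @rdname findSubsequence
setMethod("findSubsequence", "character", function(parent, query, chain) {
  stopifnot(nzchar(parent), nzchar(query))
  p <- regexpr(query, parent, fixed = TRUE)
  if (p < 0) NA_integer_ else as.integer(p)
})

#' @rdname findSubsequence
setMethod("findSubsequence", "PolymerStructure",
  function(parent, query, chain) {
    seq <- chainSequence(parent, chain)
    p <- findSubsequence(seq, query)
    if (is.na(p))
      return(list(found = FALSE, label_start = NA_integer_,
                  label_end = NA_integer_, auth_start = NA_integer_,
                  auth_end = NA_integer_))
    rt <- residueTable(parent, chain)
    e <- p + nchar(query) - 1L
    list(found = TRUE, label_start = p, label_end = e,
         auth_start = rt$resno[p], auth_end = rt$resno[e])
  })

#' Write a structure as PDB
#'
#' Writes the polymer model back to a PDB file (via \pkg{bio3d}). Re-reading
#' the file reproduces residue names, atom names and coordinates to the PDB
#' field precision of 1e-3 Angstrom. Files exceeding the fixed-width format
#' capacity (more than 99999 atoms, or coordinates outside (-1000, 10000))
#' are refused.
#'
#' @param s a \linkS4class{PolymerStructure}.
#' @param path output file path.
#' @param format only `"pdb"` is supported.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(s, path, format = "pdb") {
  stopifnot(is(s, "PolymerStructure"))
  format <- match.arg(format, "pdb")
  a <- s@atoms
  if (nrow(a) > 99999L)
    stop("format capacity: PDB supports at most 99999 atoms (have ",
         nrow(a), ")")
  xyz <- c(a$x, a$y, a$z)
  if (any(xyz >= 1e4 | xyz <= -1e3))
    stop("field width: PDB coordinates must lie in (-999.999, 9999.999)")
  if (any(nchar(a$chain) > 1L))
    stop("PDB chain identifiers must be a single character")
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
      resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
      elety = a$elety, chain = a$chain,
      insert = ifelse(nzchar(a$insert), a$insert, NA),
      o = a$o, b = rep(0, nrow(a)), elesy = a$element)
    TRUE
  }, error = function(e) {
    stop("cannot write '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}
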