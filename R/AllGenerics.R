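#' @rdname PolymerStructure-class
#' @param x,object a \linkS4class{PolymerStructure} (or other object for the
#'   accessor generics).
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname chainSequence
#' @export
setGeneric("chainSequence", function(x, chain, ...) standardGeneric("chainSequence"))

#' @rdname PolymerStructure-class
#' @export
setGeneric("residueTable", function(x, chain = NULL) standardGeneric("residueTable"))

#' @rdname PolymerStructure-class
#' @param label_ids optional integer vector restricting to these residues.
#' @export
setGeneric("caCoords", function(x, chain, label_ids = NULL) standardGeneric("caCoords"))

#' @rdname SuperpositionResult-class
#' @export
setGeneric("rmsd", function(x) standardGeneric("rmsd"))

#' @rdname SuperpositionResult-class
#' @export
setGeneric("correspondence", function(x) standardGeneric("correspondence"))

#' @rdname SecStructAssignment-class
#' @export
setGeneric("ssLabels", function(x) standardGeneric("ssLabels"))

#' @rdname PeptideSpec
#' @export
setGeneric("peptideSequence", function(x) standardGeneric("peptideSequence"))

#' @rdname MassResult-class
#' @export
setGeneric("monoMH", function(x) standardGeneric("monoMH"))

#' @rdname MassResult-class
#' @export
setGeneric("monoNeutral", function(x) standardGeneric("monoNeutral"))

#' @rdname DoseResponseFit-class
#' @export
setGeneric("ec50", function(x) standardGeneric("ec50"))

#' @rdname DecayFit-class
#' @export
setGeneric("halfLife", function(x) standardGeneric("halfLife"))

setMethod("rmsd", "SuperpositionResult", function(x) x@rmsd)
setMethod("correspondence", "SuperpositionResult", function(x) x@correspondence)
setMethod("ssLabels", "SecStructAssignment", function(x) x@labels)
setMethod("peptideSequence", "PeptideSpec", function(x) x@sequence)
setMethod("peptideSequence", "GraftDesign", function(x) x@chimera@sequence)
setMethod("monoMH", "MassResult", function(x) x@monoMH)
setMethod("monoNeutral", "MassResult", function(x) x@monoNeutral)
setMethod("ec50", "DoseResponseFit", function(x) x@ec50)
setMethod("halfLife", "DecayFit", function(x) x@halfLife)

setMethod("show", "PolymerStructure", function(object) {
  rt <- residueTable(object)
  cat(sprintf("PolymerStructure '%s': %d chain(s), %d residues, %d atoms\n",
              object@id, length(chainIds(object)), nrow(rt),
              nrow(object@atoms)))
  for (ch in chainIds(object)) {
    s <- chainSequence(object, ch)
    if (nchar(s) > 50) s <- paste0(substr(s, 1, 47), "...")
    cat(sprintf("  chain %s (%d res): %s\n", ch,
                sum(rt$chain == ch), s))
  }
})

setMethod("show", "SecStructAssignment", function(object) {
  cat(sprintf("SecStructAssignment chain %s (%d residues)\n  %s\n",
              object@chain, length(object@labels),
              paste(object@labels, collapse = "")))
})

setMethod("show", "HLHMotif", function(object) {
  cat(sprintf(
    "HLHMotif [%s chain %s]: helix1 %d-%d | loop %d-%d | helix2 %d-%d (label_id)\n",
    object@source, object@chain, object@helix1[1], object@helix1[2],
    object@loop[1], object@loop[2], object@helix2[1], object@helix2[2]))
})

setMethod("show", "DisulfidePattern", function(object) {
  if (nrow(object@pairs) == 0L) {
    cat("DisulfidePattern: no disulfides\n")
  } else {
    cat(sprintf("DisulfidePattern: %s\n", object@roman))
  }
})

setMethod("show", "ScaffoldCandidate", function(object) {
  cat(sprintf(
    "ScaffoldCandidate %s/%s: %d aa, %d Cys, %d HLH motif(s), SS: %s\n",
    object@source, object@chain, object@length, object@nCys,
    length(object@motif),
    if (nzchar(object@disulfides@roman)) object@disulfides@roman else "none"))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult (%s): rmsd = %s over %d residues\n",
              object@mode,
              if (is.na(object@rmsd)) "NA" else sprintf("%.3f A", object@rmsd),
              nrow(object@correspondence)))
})

setMethod("show", "PeptideSpec", function(object) {
  nt <- if (object@nTerm == "acetyl") "Ac-" else ""
  ct <- if (object@cTerm == "amide") "-NH2" else ""
  cat(sprintf("PeptideSpec: %s%s%s (%d aa, %d disulfide(s))\n",
              nt, object@sequence, ct, nchar(object@sequence),
              object@nDisulfides))
})

setMethod("show", "GraftDesign", function(object) {
  cat(sprintf("GraftDesign '%s': span %d-%d <- '%s'\n  chimera: %s\n",
              object@name, object@span[1], object@span[2], object@insert,
              object@chimera@sequence))
})

setMethod("show", "MassResult", function(object) {
  cat(sprintf(paste0("MassResult: mono M = %.4f, mono [M+H]+ = %.4f, ",
                     "avg M = %.3f, avg [M+H]+ = %.3f Da\n"),
              object@monoNeutral, object@monoMH, object@avgNeutral,
              object@avgMH))
})

setMethod("show", "ConservationProfile", function(object) {
  cat(sprintf(
    "ConservationProfile: %d sequences x %d columns, mean IC = %.2f bits\n",
    object@nSequences, ncol(object@freq), mean(object@ic, na.rm = TRUE)))
})

setMethod("show", "DoseResponseFit", function(object) {
  if (object@converged) {
    cat(sprintf(
      "DoseResponseFit: EC50 = %.4g, bottom = %.1f, top = %d, slope = %d\n",
      object@ec50, object@bottom, object@top, object@slope))
  } else {
    cat(sprintf("DoseResponseFit: not converged (%s)\n", object@reason))
  }
})

setMethod("show", "DecayFit", function(object) {
  if (object@converged) {
    cat(sprintf("DecayFit: t1/2 = %.3g h (k = %.4g /h, plateau = %.1f%%)\n",
                object@halfLife, object@k, object@plateau))
  } else {
    lbl <- if (nzchar(object@censorLabel))
      sprintf(" [t1/2 %s h]", object@censorLabel) else ""
    cat(sprintf("DecayFit: not converged (%s)%s\n", object@reason, lbl))
  }
})
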