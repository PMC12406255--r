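.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.as_seq_chars <- function(alignment) {
  if (methods::is(alignment, "AAStringSet"))
    alignment <- as.character(alignment)
  stopifnot(is.character(alignment), length(alignment) >= 1L)
  L <- unique(nchar(alignment))
  if (length(L) != 1L)
    stop("ragged alignment: sequences have lengths ",
         paste(sort(L), collapse = ", "))
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  bad <- setdiff(unique(as.vector(mat)), c(.AA20, "-"))
  if (length(bad))
    stop("alphabet must be the 20 amino acids plus '-'; found: ",
         paste(bad, collapse = " "))
  mat
}

#' Per-column conservation profile of a pre-aligned sequence set
#'
#' Computes, for every column of an equal-length alignment, the residue
#' frequency vector (gap tallied separately), the Shannon entropy in bits of
#' the non-gap residue distribution, the information content
#' \eqn{IC = \log_2 20 - H} (clipped at 0), and the consensus residue (ties
#' broken alphabetically). This is the computation behind a sequence logo.
#'
#' @param alignment character vector of equal-length sequences (or an
#'   `AAStringSet`); alphabet = 20 amino acids plus `-`.
#' @param correction apply the WebLogo-style small-sample correction
#'   \eqn{e_n = 19 / (2 n \ln 2)} subtracted from the IC (default off).
#' @return A \linkS4class{ConservationProfile}.
#' @examples
#' p <- conservationProfile(c("ED", "EE"))
#' p@ic  # column 1: log2(20); column 2: log2(20) - 1
#' @export
conservationProfile <- function(alignment, correction = FALSE) {
  mat <- .as_seq_chars(alignment)
  n <- nrow(mat); L <- ncol(mat)
  freq <- matrix(0, nrow = 21L, ncol = L,
                 dimnames = list(c(.AA20, "-"), NULL))
  entropy <- ic <- gapfrac <- numeric(L)
  consensus <- character(L)
  en <- if (correction) 19 / (2 * n * log(2)) else 0
  for (j in seq_len(L)) {
    tab <- table(factor(mat[, j], levels = c(.AA20, "-")))
    freq[, j] <- as.numeric(tab) / n
    gapfrac[j] <- freq["-", j]
    nongap <- as.numeric(tab[.AA20])
    tot <- sum(nongap)
    if (tot == 0) {
      entropy[j] <- NA_real_; ic[j] <- 0; consensus[j] <- NA_character_
      next
    }
    pr <- nongap / tot
    pr <- pr[pr > 0]
    entropy[j] <- -sum(pr * log2(pr))
    ic[j] <- max(0, log2(20) - entropy[j] - en)
    consensus[j] <- .AA20[which.max(nongap)]  # which.max: first = alphabetical
  }
  new("ConservationProfile", nSequences = n, freq = freq,
      entropy = entropy, ic = ic, consensus = consensus,
      gapFraction = gapfrac, correction = correction)
}

#' Export a logo height matrix
#'
#' Writes a TSV with one row per alignment position and one column per amino
#' acid, suitable for any logo renderer. With `heights = "bits"` each cell
#' is the residue's non-gap frequency times the column information content
#' (so a fully conserved column carries a single non-zero height equal to
#' its IC); with `heights = "frequency"` the cell is the plain non-gap
#' frequency.
#'
#' @param p a \linkS4class{ConservationProfile}.
#' @param path output TSV path.
#' @param heights `"bits"` or `"frequency"`.
#' @return The height matrix (positions x 20), invisibly.
#' @export
exportLogoMatrix <- function(p, path, heights = c("bits", "frequency")) {
  heights <- match.arg(heights)
  stopifnot(is(p, "ConservationProfile"))
  L <- ncol(p@freq)
  nongap <- p@freq[.AA20, , drop = FALSE]
  tot <- colSums(nongap)
  rel <- sweep(nongap, 2, ifelse(tot > 0, tot, 1), "/")
  h <- if (heights == "bits") sweep(rel, 2, p@ic, "*") else rel
  h[, tot == 0] <- 0
  out <- data.frame(position = seq_len(L), t(h), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(t(h))
}
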