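#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid transform mapping the mobile coordinate set `P` onto
#' the fixed set `Q` (paired row order), via SVD of the cross-covariance
#' matrix with the determinant sign correction that guarantees a proper
#' rotation (no reflection). RMSD is the root mean squared deviation of the
#' transformed `P` from `Q`.
#'
#' @param P,Q n x 3 coordinate matrices, n >= 3, rows paired.
#' @param correspondence optional integer matrix recorded in the result
#'   (defaults to the row pairing 1..n).
#' @param mode mode string recorded in the result.
#' @return A \linkS4class{SuperpositionResult}. `details$ill_conditioned` is
#'   `TRUE` for degenerate (e.g. collinear) inputs.
#' @examples
#' P <- matrix(rnorm(30), ncol = 3)
#' kabsch(P, P)@rmsd  # 0
#' @export
kabsch <- function(P, Q, correspondence = NULL, mode = "all_atom_ca") {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3L || ncol(Q) != 3L)
    stop("P and Q must be paired n x 3 matrices")
  n <- nrow(P)
  if (n < 3L) stop("need at least 3 paired points (have ", n, ")")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(cq - R %*% cp)
  dev <- Pc %*% t(R) - Qc
  r <- sqrt(mean(rowSums(dev^2)))
  # collinear/degenerate input: second singular value vanishes
  ill <- sv$d[2] <= 1e-8 * max(sv$d[1], .Machine$double.eps)
  if (is.null(correspondence))
    correspondence <- cbind(query = seq_len(n), candidate = seq_len(n))
  new("SuperpositionResult", rotation = R, translation = trans, rmsd = r,
      correspondence = correspondence, mode = mode,
      details = list(ill_conditioned = ill))
}

#' Apply a superposition transform to coordinates
#'
#' @param res a \linkS4class{SuperpositionResult}.
#' @param X n x 3 coordinates.
#' @return Transformed n x 3 coordinates.
#' @export
applyTransform <- function(res, X) {
  X <- as.matrix(X)
  sweep(X %*% t(res@rotation), 2, res@translation, "+")
}

.motif_ca <- function(s, motif, span) {
  caCoords(s, motif@chain, label_ids = seq(span[1], span[2]))
}

#' Framework-constrained motif superposition
#'
#' Sequence-independent superposition of two helix-loop-helix motifs using
#' only their helical frameworks: for each helix pair (helix1 to helix1,
#' helix2 to helix2) the shorter helix's C-alpha window slides along the
#' longer one, and the pair of offsets minimizing the joint Kabsch RMSD over
#' the union of both helices is chosen exhaustively. Loop residues are
#' excluded from the fit, leaving the loop conformation free; when the two
#' loops have equal length their post-transform RMSD is reported separately
#' in `details$loop_rmsd`.
#'
#' @param query_s,cand_s \linkS4class{PolymerStructure}s.
#' @param query_m,cand_m \linkS4class{HLHMotif}s on those structures.
#' @return A \linkS4class{SuperpositionResult} (mode `"framework"`);
#'   `details$offsets` records the chosen helix offsets,
#'   `details$aligned_length` the number of fitted residues.
#' @export
frameworkAlign <- function(query_s, query_m, cand_s, cand_m) {
  stopifnot(is(query_m, "HLHMotif"), is(cand_m, "HLHMotif"))
  qh <- list(.motif_ca(query_s, query_m, query_m@helix1),
             .motif_ca(query_s, query_m, query_m@helix2))
  ch <- list(.motif_ca(cand_s, cand_m, cand_m@helix1),
             .motif_ca(cand_s, cand_m, cand_m@helix2))
  for (h in c(qh, ch)) if (nrow(h) < 4L)
    stop("helices must have at least 4 residues")

  # per-helix index pairings for a given offset of the shorter window
  pairings <- function(nq, nc, off) {
    m <- min(nq, nc)
    if (nq <= nc) cbind(q = seq_len(m), c = seq_len(m) + off)
    else cbind(q = seq_len(m) + off, c = seq_len(m))
  }
  off_range <- function(nq, nc) 0:abs(nq - nc)

  best <- NULL
  for (o1 in off_range(nrow(qh[[1]]), nrow(ch[[1]]))) {
    p1 <- pairings(nrow(qh[[1]]), nrow(ch[[1]]), o1)
    for (o2 in off_range(nrow(qh[[2]]), nrow(ch[[2]]))) {
      p2 <- pairings(nrow(qh[[2]]), nrow(ch[[2]]), o2)
      P <- rbind(qh[[1]][p1[, "q"], , drop = FALSE],
                 qh[[2]][p2[, "q"], , drop = FALSE])
      Q <- rbind(ch[[1]][p1[, "c"], , drop = FALSE],
                 ch[[2]][p2[, "c"], , drop = FALSE])
      fit <- kabsch(P, Q)
      if (is.null(best) || fit@rmsd < best$rmsd - 1e-12) {
        best <- list(rmsd = fit@rmsd, fit = fit, o = c(o1, o2),
                     p1 = p1, p2 = p2)
      }
    }
  }
  corr <- cbind(
    query = c(seq(query_m@helix1[1], query_m@helix1[2])[best$p1[, "q"]],
              seq(query_m@helix2[1], query_m@helix2[2])[best$p2[, "q"]]),
    candidate = c(seq(cand_m@helix1[1], cand_m@helix1[2])[best$p1[, "c"]],
                  seq(cand_m@helix2[1], cand_m@helix2[2])[best$p2[, "c"]]))
  details <- list(offsets = best$o, aligned_length = nrow(corr),
                  ill_conditioned = best$fit@details$ill_conditioned)
  qll <- diff(query_m@loop) + 1L; cll <- diff(cand_m@loop) + 1L
  if (qll == cll) {
    ql <- .motif_ca(query_s, query_m, query_m@loop)
    cl <- .motif_ca(cand_s, cand_m, cand_m@loop)
    tl <- applyTransform(best$fit, ql)
    details$loop_rmsd <- sqrt(mean(rowSums((tl - cl)^2)))
  }
  new("SuperpositionResult", rotation = best$fit@rotation,
      translation = best$fit@translation, rmsd = best$rmsd,
      correspondence = corr, mode = "framework", details = details)
}

.frag_dists <- function(X, i, frag) {
  # condensed intra-fragment distance vector for the fragment starting at i
  idx <- i:(i + frag - 1L)
  as.vector(dist(X[idx, , drop = FALSE]))
}

#' Combinatorial-extension-style chain alignment
#'
#' Sequence-independent alignment built from 8-residue aligned fragment
#' pairs (AFPs). A fragment pair is admissible when the mean absolute
#' difference of the two intra-fragment C-alpha distance matrices is at most
#' `d0`; a dynamic program chains non-overlapping admissible pairs whose
#' inter-fragment distance matrices also agree within `d0`, maximizing the
#' aligned length. The best path is refined by a single Kabsch fit over all
#' aligned residues.
#'
#' @param P,Q n x 3 C-alpha coordinate matrices (>= 8 residues each).
#' @param frag fragment length (8).
#' @param d0 distance-matrix similarity threshold, Angstrom.
#' @return A \linkS4class{SuperpositionResult} (mode `"ce_style"`). When no
#'   admissible fragment pair exists, `rmsd` is `NA` and
#'   `details$aligned = FALSE` ("no alignment" is a result, not an error).
#' @export
ceStyleAlign <- function(P, Q, frag = 8L, d0 = 3.0) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) < frag || nrow(Q) < frag)
    stop("both chains need at least ", frag, " residues")
  np <- nrow(P) - frag + 1L
  nq <- nrow(Q) - frag + 1L
  dp_vecs <- lapply(seq_len(np), function(i) .frag_dists(P, i, frag))
  dq_vecs <- lapply(seq_len(nq), function(k) .frag_dists(Q, k, frag))
  afp <- NULL
  for (i in seq_len(np)) for (k in seq_len(nq)) {
    sim <- mean(abs(dp_vecs[[i]] - dq_vecs[[k]]))
    if (sim <= d0) afp <- rbind(afp, c(i = i, k = k, s = sim))
  }
  no_alignment <- function(reason) {
    new("SuperpositionResult", rotation = diag(3), translation = numeric(3),
        rmsd = NA_real_,
        correspondence = matrix(integer(0), ncol = 2,
                                dimnames = list(NULL, c("query",
                                                        "candidate"))),
        mode = "ce_style", details = list(aligned = FALSE, reason = reason))
  }
  if (is.null(afp)) return(no_alignment("no admissible fragment pair"))
  afp <- afp[order(afp[, "i"], afp[, "k"]), , drop = FALSE]
  m <- nrow(afp)
  # inter-fragment compatibility of consecutive path members
  compat <- function(a, b) {
    ia <- afp[a, "i"]:(afp[a, "i"] + frag - 1L)
    ib <- afp[b, "i"]:(afp[b, "i"] + frag - 1L)
    ka <- afp[a, "k"]:(afp[a, "k"] + frag - 1L)
    kb <- afp[b, "k"]:(afp[b, "k"] + frag - 1L)
    dP <- sqrt(pmax(outer(rowSums(P[ia, , drop = FALSE]^2),
                          rowSums(P[ib, , drop = FALSE]^2), "+") -
                    2 * P[ia, , drop = FALSE] %*% t(P[ib, , drop = FALSE]),
                    0))
    dQ <- sqrt(pmax(outer(rowSums(Q[ka, , drop = FALSE]^2),
                          rowSums(Q[kb, , drop = FALSE]^2), "+") -
                    2 * Q[ka, , drop = FALSE] %*% t(Q[kb, , drop = FALSE]),
                    0))
    mean(abs(dP - dQ))
  }
  # DP: longest chain of non-overlapping AFPs; the path score accumulates
  # both intra-fragment and inter-fragment dissimilarity, so that on
  # internally periodic structures (helices) register-consistent paths win
  len <- rep(1L, m); tot <- afp[, "s"]; prev <- rep(0L, m)
  for (b in seq_len(m)) {
    for (a in seq_len(b - 1L)) {
      if (afp[a, "i"] + frag <= afp[b, "i"] &&
          afp[a, "k"] + frag <= afp[b, "k"]) {
        cross <- compat(a, b)
        if (cross > d0) next
        cand_len <- len[a] + 1L
        cand_tot <- tot[a] + afp[b, "s"] + cross
        if (cand_len > len[b] ||
            (cand_len == len[b] && cand_tot < tot[b])) {
          len[b] <- cand_len; tot[b] <- cand_tot; prev[b] <- a
        }
      }
    }
  }
  # longest path; ties by smallest cumulative dissimilarity
  cands <- which(len == max(len))
  end <- cands[which.min(tot[cands])]
  path <- integer(0)
  node <- end
  while (node != 0L) { path <- c(node, path); node <- prev[node] }
  qi <- unlist(lapply(path, function(p) afp[p, "i"]:(afp[p, "i"] + frag - 1L)))
  ki <- unlist(lapply(path, function(p) afp[p, "k"]:(afp[p, "k"] + frag - 1L)))
  fit <- kabsch(P[qi, , drop = FALSE], Q[ki, , drop = FALSE],
                correspondence = cbind(query = qi, candidate = ki),
                mode = "ce_style")
  fit@details <- c(fit@details,
                   list(aligned = TRUE, n_fragments = length(path)))
  fit
}

#' Rank scaffold candidates against a query motif
#'
#' Aligns each candidate to the query and returns a ranking table, sorted by
#' ascending RMSD, ties broken by aligned length (longer first) then source
#' id. Candidates without a usable motif are skipped with a logged reason.
#'
#' @param query_s query \linkS4class{PolymerStructure}.
#' @param query_m query \linkS4class{HLHMotif}.
#' @param library list of \linkS4class{ScaffoldCandidate}, or a list of
#'   lists with elements `structure`, `motif`, `source`.
#' @param structures named list of \linkS4class{PolymerStructure} keyed by
#'   source id (required when `library` holds `ScaffoldCandidate`s).
#' @param mode `"framework"` or `"ce_style"`.
#' @return data.frame with columns `source`, `mode`, `rmsd`,
#'   `aligned_length`; skipped candidates are recorded in
#'   `attr(, "skipped")`.
#' @export
rankCandidates <- function(query_s, query_m, library, structures = NULL,
                           mode = c("framework", "ce_style")) {
  mode <- match.arg(mode)
  stopifnot(length(library) > 0L)
  rows <- list(); skipped <- character(0)
  for (entry in library) {
    if (is(entry, "ScaffoldCandidate")) {
      src <- entry@source
      st <- structures[[src]]
      if (is.null(st)) {
        skipped <- c(skipped, sprintf("%s: structure not supplied", src))
        next
      }
      mt <- if (length(entry@motif)) entry@motif[[1]] else NULL
      chain <- entry@chain
    } else {
      src <- entry$source; st <- entry$structure; mt <- entry$motif
      chain <- if (!is.null(mt)) mt@chain else chainIds(st)[1]
    }
    if (mode == "framework") {
      if (is.null(mt)) {
        skipped <- c(skipped, sprintf("%s: no helix-loop-helix motif", src))
        next
      }
      res <- frameworkAlign(query_s, query_m, st, mt)
    } else {
      span <- c(query_m@helix1[1], query_m@helix2[2])
      qca <- caCoords(query_s, query_m@chain,
                      label_ids = seq(span[1], span[2]))
      res <- ceStyleAlign(qca, caCoords(st, chain))
      if (!isTRUE(res@details$aligned)) {
        skipped <- c(skipped, sprintf("%s: no ce-style alignment", src))
        next
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      source = src, mode = mode, rmsd = res@rmsd,
      aligned_length = nrow(res@correspondence),
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(0), mode = character(0),
               rmsd = numeric(0), aligned_length = integer(0))
  tab <- tab[order(tab$rmsd, -tab$aligned_length, tab$source), ,
             drop = FALSE]
  rownames(tab) <- NULL
  if (length(skipped)) message("skipped: ", paste(skipped, collapse = "; "))
  attr(tab, "skipped") <- skipped
  tab
}
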