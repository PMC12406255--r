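# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Canonical alpha-helix C-alpha coordinates
#'
#' Ideal helix on a cylinder: 1.5 Angstrom rise and 100 degrees twist per
#' residue at radius 2.3 Angstrom by default, which reproduces the canonical
#' C-alpha distance signature d(i,i+3) of about 5.1 and d(i,i+4) of about
#' 6.2 Angstrom.
#'
#' @param n residue count.
#' @param rise rise per residue, Angstrom.
#' @param twist twist per residue, degrees.
#' @param radius helix radius, Angstrom.
#' @return n x 3 coordinate matrix.
#' @export
helixCoords <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  stopifnot(n >= 1, rise > 0, radius > 0)
  t <- seq_len(n) - 1L
  th <- twist * pi / 180 * t
  cbind(x = radius * cos(th), y = radius * sin(th), z = rise * t)
}

#' Helix-loop-helix fixture recipe
#'
#' Parameters for [buildHLH()]: two canonical helices joined by a smooth
#' circular-arc loop with C-alpha spacing clamped near 3.8 Angstrom,
#' optional cysteines with planted disulfide staples, Gaussian coordinate
#' noise, and a seeded rigid transform.
#'
#' @param helix1,helix2 helix lengths (residues, >= 4).
#' @param loop loop length (residues, >= 1).
#' @param rise,twist,radius canonical helix parameters, see
#'   [helixCoords()].
#' @param cys_positions sequence positions that are cysteine.
#' @param ss_pairs two-column matrix of sequence positions (subset of
#'   `cys_positions`) to staple at S-gamma distance 2.05 Angstrom.
#' @param noise_sigma Gaussian coordinate noise, expressed as the RMS
#'   positional displacement per atom, Angstrom (the crystallographic
#'   "coordinate error" convention; per-axis SD is `noise_sigma/sqrt(3)`).
#' @param transform apply a random rigid transform.
#' @param seed RNG seed for noise and transform (one global stream).
#' @return Named list (recipe).
#' @export
hlhRecipe <- function(helix1 = 10L, loop = 5L, helix2 = 10L, rise = 1.5,
                      twist = 100, radius = 2.3,
                      cys_positions = integer(0), ss_pairs = NULL,
                      noise_sigma = 0, transform = FALSE, seed = NULL) {
  stopifnot(helix1 >= 4L, helix2 >= 4L)
  if (loop < 1L)
    stop("loop length must be >= 1: joining the helix ends directly ",
         "clashes the canonical geometries")
  if (!is.null(ss_pairs)) {
    ss_pairs <- matrix(as.integer(ss_pairs), ncol = 2)
    if (!all(ss_pairs %in% cys_positions))
      stop("ss_pairs must reference cys_positions")
  }
  n <- helix1 + loop + helix2
  stopifnot(all(cys_positions >= 1 & cys_positions <= n))
  list(helix1 = as.integer(helix1), loop = as.integer(loop),
       helix2 = as.integer(helix2), rise = rise, twist = twist,
       radius = radius, cys_positions = as.integer(cys_positions),
       ss_pairs = ss_pairs, noise_sigma = noise_sigma,
       transform = transform, seed = seed)
}

.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Build a helix-loop-helix fixture with ground truth
#'
#' Generates C-alpha coordinates for two canonical helices joined by a
#' circular-arc loop (consecutive C-alpha spacing stays within 3.8 +/- 0.2
#' Angstrom), plants C-beta/S-gamma atoms for the requested cysteines (with
#' stapled pairs placed at exactly 2.05 Angstrom S-gamma separation), adds
#' Gaussian coordinate noise and a seeded rigid transform when requested,
#' and returns the structure together with its ground-truth annotation.
#'
#' @param recipe see [hlhRecipe()].
#' @param id structure identifier.
#' @return List: `structure` (\linkS4class{PolymerStructure}), `labels`
#'   (true H/C labels), `motif` (true \linkS4class{HLHMotif}),
#'   `ss_pairs` (planted pairs in cysteine ordinals), `recipe`.
#' @examples
#' fx <- buildHLH(hlhRecipe(10, 5, 10))
#' table(fx$labels)
#' @export
buildHLH <- function(recipe = hlhRecipe(), id = "hlh_fixture") {
  n1 <- recipe$helix1; nl <- recipe$loop; n2 <- recipe$helix2
  n <- n1 + nl + n2
  .with_seed(recipe$seed, {
    h1 <- helixCoords(n1, recipe$rise, recipe$twist, recipe$radius)
    # loop: circular arc bending pi over (loop + 1) steps of 3.8 Angstrom,
    # turning in the x-z plane from the helix-1 axis direction (+z)
    step <- 3.8
    phi <- pi / (nl + 1L)
    dirs <- vapply(seq_len(nl + 1L), function(k)
      c(sin(k * phi), 0, cos(k * phi)), numeric(3))
    pts <- matrix(NA_real_, nl + 1L, 3L)
    prev <- h1[n1, ]
    for (k in seq_len(nl + 1L)) {
      prev <- prev + step * dirs[, k]
      pts[k, ] <- prev
    }
    loop_ca <- pts[seq_len(nl), , drop = FALSE]
    h2_start <- pts[nl + 1L, ]
    # helix 2: canonical helix flipped to run antiparallel, anchored at the
    # end of the loop arc
    R2 <- rbind(c(cos(pi), 0, sin(pi)), c(0, 1, 0), c(-sin(pi), 0, cos(pi)))
    h2 <- helixCoords(n2, recipe$rise, recipe$twist, recipe$radius)
    h2 <- sweep(h2 %*% t(R2), 2, h2_start - as.numeric(R2 %*% h2[1, ]), "+")
    ca <- rbind(h1, loop_ca, h2)

    if (recipe$noise_sigma > 0)
      # noise_sigma is the RMS positional displacement per atom (the usual
      # "coordinate error" convention), i.e. sigma/sqrt(3) per axis
      ca <- ca + matrix(stats::rnorm(3 * n, sd = recipe$noise_sigma /
                                       sqrt(3)), n, 3)

    resid <- rep("ALA", n)
    resid[recipe$cys_positions] <- "CYS"
    atoms <- data.frame(chain = "A", resno = seq_len(n), resid = resid,
                        elety = "CA", x = ca[, 1], y = ca[, 2], z = ca[, 3],
                        stringsAsFactors = FALSE)
    # side-chain atoms for cysteines
    paired <- if (!is.null(recipe$ss_pairs)) as.vector(recipe$ss_pairs)
              else integer(0)
    add_atom <- function(resno, name, xyz) {
      atoms <<- rbind(atoms, data.frame(
        chain = "A", resno = resno, resid = "CYS", elety = name,
        x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE))
    }
    if (!is.null(recipe$ss_pairs)) {
      for (r in seq_len(nrow(recipe$ss_pairs))) {
        i <- recipe$ss_pairs[r, 1]; j <- recipe$ss_pairs[r, 2]
        m <- (ca[i, ] + ca[j, ]) / 2
        u <- (ca[j, ] - ca[i, ])
        u <- u / sqrt(sum(u^2))
        add_atom(i, "CB", ca[i, ] + 1.53 * (m - ca[i, ]) /
                   sqrt(sum((m - ca[i, ])^2)))
        add_atom(i, "SG", m - 1.025 * u)
        add_atom(j, "CB", ca[j, ] + 1.53 * (m - ca[j, ]) /
                   sqrt(sum((m - ca[j, ])^2)))
        add_atom(j, "SG", m + 1.025 * u)
      }
    }
    for (i in setdiff(recipe$cys_positions, paired)) {
      u <- ca[i, ] - c(0, 0, ca[i, 3])  # radial-ish outward
      if (sum(u^2) < 1e-6) u <- c(1, 0, 0)
      u <- u / sqrt(sum(u^2))
      add_atom(i, "CB", ca[i, ] + 1.53 * u)
      add_atom(i, "SG", ca[i, ] + 3.3 * u)
    }
    if (recipe$transform) {
      R <- .random_rotation()
      tr <- stats::runif(3, -20, 20)
      xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
      atoms$x <- xyz[, 1] + tr[1]
      atoms$y <- xyz[, 2] + tr[2]
      atoms$z <- xyz[, 3] + tr[3]
    }
    # order atoms by residue so label_id assignment follows the chain
    atoms <- atoms[order(atoms$resno, match(atoms$elety,
                                            c("CA", "CB", "SG"))), ]
    s <- PolymerStructure(id, atoms,
                          metadata = list(recipe = recipe))
    labels <- c(rep("H", n1), rep("C", nl), rep("H", n2))
    motif <- new("HLHMotif", chain = "A", helix1 = c(1L, n1),
                 loop = c(n1 + 1L, n1 + nl),
                 helix2 = c(n1 + nl + 1L, n), source = id)
    ss_ord <- if (!is.null(recipe$ss_pairs)) {
      cys_sorted <- sort(recipe$cys_positions)
      t(apply(recipe$ss_pairs, 1, function(p)
        sort(match(p, cys_sorted))))
    } else matrix(integer(0), ncol = 2)
    list(structure = s, labels = labels, motif = motif,
         ss_pairs = ss_ord, recipe = recipe)
  })
}

# deterministic length -> (helix1, loop, helix2) decomposition
.hlh_split <- function(len) {
  h <- (len - 1L) %/% 2L
  c(h, len - 2L * h, h)
}

#' Build a synthetic scaffold library with a truth table
#'
#' Generates a deterministic library of helix-loop-helix peptides over a
#' grid of lengths and cysteine counts chosen to exercise the curation
#' filter, including both inclusive boundaries (lengths 10 and 50 pass;
#' 9 and 51 fail) and cysteine-poor entries. For a fixed seed the output is
#' identical across runs. The default 20-entry grid has 12 entries passing
#' the filter.
#'
#' @param n number of entries (up to 20 from the default grid, or recycled
#'   beyond with incremented lengths).
#' @param seed RNG seed (drives coordinate noise).
#' @param dir optional directory; when given, one PDB per entry plus a
#'   `truth.tsv` table are written there.
#' @param noise_sigma coordinate noise applied to every entry, Angstrom.
#' @return List: `structures` (named list of
#'   \linkS4class{PolymerStructure}), `truth` (data.frame with `source`,
#'   `length`, `n_cys`, `expected_pass`, `reasons`).
#' @export
buildLibrary <- function(n = 20L, seed = 1L, dir = NULL,
                         noise_sigma = 0.15) {
  grid <- data.frame(
    length = c(9L, 10L, 14L, 20L, 27L, 33L, 42L, 50L, 51L, 60L,
               12L, 16L, 24L, 30L, 48L, 13L, 18L, 26L, 38L, 45L),
    n_cys = c(rep(4L, 10), rep(0L, 5), rep(2L, 5)))
  if (n > nrow(grid)) {
    extra <- data.frame(
      length = 14L + 2L * seq_len(n - nrow(grid)),
      n_cys = rep(c(2L, 0L), length.out = n - nrow(grid)))
    grid <- rbind(grid, extra)
  }
  grid <- grid[seq_len(n), , drop = FALSE]
  structures <- list()
  truth <- NULL
  for (i in seq_len(n)) {
    len <- grid$length[i]; ncys <- grid$n_cys[i]
    parts <- .hlh_split(len)
    cys <- switch(as.character(ncys),
                  "0" = integer(0),
                  "2" = c(2L, len - 1L),
                  "4" = c(2L, 4L, len - 3L, len - 1L))
    pairs <- switch(as.character(ncys),
                    "0" = NULL,
                    "2" = matrix(c(2L, len - 1L), ncol = 2),
                    "4" = matrix(c(2L, len - 1L, 4L, len - 3L), ncol = 2,
                                 byrow = TRUE))
    src <- sprintf("SYN%03d", i)
    fx <- buildHLH(hlhRecipe(parts[1], parts[2], parts[3],
                             cys_positions = cys, ss_pairs = pairs,
                             noise_sigma = noise_sigma,
                             seed = (seed * 131L + i) %% 2147483647L),
                   id = src)
    structures[[src]] <- fx$structure
    verdict <- scaffoldFilter(len, ncys)
    truth <- rbind(truth, data.frame(
      source = src, length = len, n_cys = ncys,
      expected_pass = verdict$pass,
      reasons = paste(verdict$reasons, collapse = ","),
      stringsAsFactors = FALSE))
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (src in names(structures))
      writeStructure(structures[[src]], file.path(dir,
                                                  paste0(src, ".pdb")))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(structures = structures, truth = truth, dir = dir)
}

#' Simulate dose-response data under the constrained three-parameter model
#'
#' Responses are drawn from
#' \eqn{Y = bottom + (100 - bottom)/(1 + 10^{\log_{10} c - \log_{10} EC_{50}})}
#' plus Gaussian noise; the generator is the exact inverse of [fitEC50()].
#'
#' @param ec50 true EC50 (same units as `concentrations`).
#' @param bottom true lower plateau, % of control.
#' @param concentrations concentration grid; defaults to the standard
#'   8-point half-log (3.16-fold) dilution series placed so the EC50 sits
#'   mid-series.
#' @param sigma Gaussian noise SD, percentage points.
#' @param n_reps independent replicates per concentration (default 5,
#'   mirroring dose-response assays averaged over 3--5 independent
#'   experiments).
#' @param seed RNG seed.
#' @return data.frame with `concentration`, `rep`, `response`.
#' @export
simulateDoseResponse <- function(ec50, bottom,
                                 concentrations =
                                   ec50 * 10^seq(-1.5, 2, by = 0.5),
                                 sigma = 0, n_reps = 5L, seed = NULL) {
  stopifnot(ec50 > 0)
  mu <- .dr_model(log10(concentrations), log10(ec50), bottom)
  .with_seed(seed, {
    out <- expand.grid(rep = seq_len(n_reps),
                       concentration = concentrations)
    out$response <- rep(mu, each = n_reps) +
      stats::rnorm(nrow(out), sd = sigma)
    out[, c("concentration", "rep", "response")]
  })
}

#' Simulate a serum-decay time series
#'
#' One-phase exponential decay
#' \eqn{Y = (100 - plateau) e^{-kt} + plateau} with \eqn{k = \ln 2 /
#' t_{1/2}}, plus Gaussian noise on all points after t = 0 (the t = 0 point
#' is the 100% normalization reference and stays exact).
#'
#' @param half_life true half-life, h.
#' @param times sampling times, h (must include 0).
#' @param plateau asymptote, %.
#' @param sigma Gaussian noise SD, percentage points.
#' @param n_reps replicates per time point (default 2, matching duplicate
#'   serum-stability determinations).
#' @param seed RNG seed.
#' @return data.frame with `time`, `rep`, `remaining`.
#' @export
simulateDecay <- function(half_life, times = c(0, 1, 2, 4, 8, 24, 36, 48),
                          plateau = 0, sigma = 0, n_reps = 2L,
                          seed = NULL) {
  stopifnot(half_life > 0, any(times == 0))
  k <- log(2) / half_life
  mu <- (100 - plateau) * exp(-k * times) + plateau
  .with_seed(seed, {
    out <- expand.grid(rep = seq_len(n_reps), time = times)
    out$remaining <- rep(mu, each = n_reps)
    jitter <- out$time > 0
    out$remaining[jitter] <- out$remaining[jitter] +
      stats::rnorm(sum(jitter), sd = sigma)
    out[, c("time", "rep", "remaining")]
  })
}

#' Column probability matrices for alignment simulation
#'
#' `uniformProfileMatrix(length)` gives every column the uniform
#' distribution over the 20 amino acids; `conservedProfileMatrix(sequence,
#' weight)` gives each column probability `weight` at the stated residue and
#' spreads the remainder uniformly over the other 19.
#'
#' @param length number of columns.
#' @param sequence consensus sequence (1-letter, 20 standard residues).
#' @param weight probability mass on the consensus residue, in [1/20, 1].
#' @return length x 20 probability matrix (columns named by residue).
#' @export
uniformProfileMatrix <- function(length) {
  matrix(1 / 20, nrow = length, ncol = 20,
         dimnames = list(NULL, .AA20))
}

#' @rdname uniformProfileMatrix
#' @export
conservedProfileMatrix <- function(sequence, weight = 1) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(all(ch %in% .AA20), weight >= 1 / 20, weight <= 1)
  m <- matrix((1 - weight) / 19, nrow = length(ch), ncol = 20,
              dimnames = list(NULL, .AA20))
  for (i in seq_along(ch)) m[i, ch[i]] <- weight
  m
}

#' Simulate a pre-aligned homolog set
#'
#' Draws each column independently from the per-position residue
#' distribution of `profile`.
#'
#' @param n_seqs number of sequences.
#' @param profile L x 20 probability matrix (rows = positions), e.g. from
#'   [uniformProfileMatrix()] or [conservedProfileMatrix()].
#' @param seed RNG seed.
#' @param path optional FASTA output path.
#' @return Character vector of sequences (named `seq_1`, ...).
#' @export
simulateAlignment <- function(n_seqs, profile, seed = NULL, path = NULL) {
  stopifnot(ncol(profile) == 20L, all(abs(rowSums(profile) - 1) < 1e-8))
  L <- nrow(profile)
  seqs <- .with_seed(seed, {
    m <- vapply(seq_len(L), function(j)
      sample(.AA20, n_seqs, replace = TRUE, prob = profile[j, ]),
      character(n_seqs))
    if (n_seqs == 1L) m <- matrix(m, nrow = 1L)
    apply(m, 1, paste, collapse = "")
  })
  names(seqs) <- paste0("seq_", seq_len(n_seqs))
  if (!is.null(path)) {
    aa <- Biostrings::AAStringSet(seqs)
    Biostrings::writeXStringSet(aa, filepath = path)
  }
  seqs
}
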