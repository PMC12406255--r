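.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# write via a .partial temp name so an aborted run never leaves a
# plausible-looking final file
.commit <- function(writer, path) {
  tmp <- paste0(path, ".partial")
  writer(tmp)
  file.rename(tmp, path)
  path
}

#' Run the scaffold-matching and grafting workflow
#'
#' Executes the full pipeline: curate a structure library (parse, filter,
#' deduplicate), rank the surviving scaffolds against a query
#' helix-loop-helix motif by framework-constrained superposition, build the
#' grafted designs from a design config, and compute their masses. Emits
#' `candidates.tsv`, `ranked.tsv`, `designs.fasta`, `masses.tsv` and a
#' `manifest.json` (package version, seed, config and output checksums)
#' into the report directory. Any stage failure aborts with the stage name;
#' partially written files keep a `.partial` suffix.
#'
#' @param out_dir report directory (created if needed).
#' @param library_dir directory of PDB/mmCIF files; when `NULL` a seeded
#'   synthetic library is generated with [buildLibrary()].
#' @param query list with `path`, `chain` and optionally `span`
#'   (label_id range to cut the motif from); when `NULL` a synthetic
#'   helix-loop-helix query is generated.
#' @param design_config path to a YAML design config; defaults to the
#'   packaged VhTI series.
#' @param seed seed for all randomness in the run.
#' @param mode alignment mode for ranking.
#' @param n_library synthetic library size when `library_dir` is `NULL`.
#' @return `out_dir`, invisibly; see the emitted files for results.
#' @export
runWorkflow <- function(out_dir, library_dir = NULL, query = NULL,
                        design_config = NULL, seed = 1L,
                        mode = c("framework", "ce_style"),
                        n_library = 20L) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(design_config))
    design_config <- system.file("extdata", "vhti_designs.yaml",
                                 package = "ScaffoldMatch", mustWork = TRUE)

  ## curate ----------------------------------------------------------------
  curated <- .stage("curate", {
    if (is.null(library_dir)) {
      lib <- buildLibrary(n = n_library, seed = seed)
      structures <- lib$structures
    } else {
      if (!dir.exists(library_dir))
        stop("library directory not found: ", library_dir)
      files <- list.files(library_dir,
                          pattern = "\\.(pdb|ent|cif|mmcif)$",
                          full.names = TRUE)
      if (!length(files)) stop("no structure files in ", library_dir)
      structures <- lapply(files, readStructure)
      names(structures) <- vapply(structures, function(s) s@id,
                                  character(1))
    }
    cands <- lapply(structures, scaffoldCandidate)
    rows <- lapply(cands, function(cd) {
      v <- scaffoldFilter(cd)
      data.frame(source = cd@source, chain = cd@chain,
                 length = cd@length, n_cys = cd@nCys, pass = v$pass,
                 reasons = paste(v$reasons, collapse = ","),
                 n_motifs = length(cd@motif),
                 disulfides = cd@disulfides@roman,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    .commit(function(p) utils::write.table(tab, p, sep = "\t",
                                           quote = FALSE,
                                           row.names = FALSE),
            file.path(out_dir, "candidates.tsv"))
    survivors <- dedupeCandidates(Filter(function(cd)
      scaffoldFilter(cd)$pass && length(cd@motif) > 0, cands))
    list(structures = structures, survivors = survivors)
  })

  ## match -----------------------------------------------------------------
  .stage("match", {
    if (is.null(query)) {
      qfx <- buildHLH(hlhRecipe(10, 5, 10, seed = seed + 1L,
                                noise_sigma = 0.1), id = "query")
      qs <- qfx$structure; qm <- qfx$motif
    } else {
      qs <- readStructure(query$path)
      chain <- query$chain %||% chainIds(qs)[1]
      labels <- assignSecStruct(qs, chain)
      motifs <- extractHLHMotifs(labels, source = qs@id)
      if (!length(motifs))
        stop("query has no helix-loop-helix motif on chain ", chain)
      qm <- motifs[[1]]
    }
    if (!length(curated$survivors))
      stop("no scaffold candidates survived curation")
    ranked <- rankCandidates(qs, qm, curated$survivors,
                             structures = curated$structures, mode = mode)
    .commit(function(p) utils::write.table(ranked, p, sep = "\t",
                                           quote = FALSE,
                                           row.names = FALSE),
            file.path(out_dir, "ranked.tsv"))
  })

  ## graft -----------------------------------------------------------------
  designs <- .stage("graft", {
    ds <- readDesignConfig(design_config)
    .commit(function(p) writeDesignFasta(ds, p),
            file.path(out_dir, "designs.fasta"))
    ds
  })

  ## mass ------------------------------------------------------------------
  .stage("mass", {
    specs <- c(designs, attr(designs, "reference"),
               list(scaffold = attr(designs, "scaffold")))
    tab <- massTable(specs)
    .commit(function(p) utils::write.table(tab, p, sep = "\t",
                                           quote = FALSE,
                                           row.names = FALSE),
            file.path(out_dir, "masses.tsv"))
  })

  ## manifest --------------------------------------------------------------
  outputs <- c("candidates.tsv", "ranked.tsv", "designs.fasta",
               "masses.tsv")
  sums <- tools::md5sum(file.path(out_dir, outputs))
  manifest <- list(
    package = "ScaffoldMatch",
    version = as.character(utils::packageVersion("ScaffoldMatch")),
    seed = seed, mode = mode,
    design_config_md5 = unname(tools::md5sum(design_config)),
    outputs = stats::setNames(unname(sums), outputs))
  manifest$hash <- unname(tools::md5sum(
    .commit(function(p) jsonlite::write_json(
      manifest[c("seed", "mode", "design_config_md5", "outputs")], p,
      auto_unbox = TRUE), file.path(out_dir, "manifest.core.json"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
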