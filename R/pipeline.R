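#' Configuration for a full pipeline run
#'
#' Either a simulation config (synthetic input) or paths to clone FASTA/TSV
#' plus a JSON gene-model file must be supplied. All thresholds of the
#' downstream stages are carried here so a run is reproducible from its
#' serialized config alone.
#'
#' @param simulation A [simulationConfig()], or `NULL` to read real input.
#' @param clonesFasta,clonesTsv,modelsJson Input paths (ignored when
#'   `simulation` is given). Validated at config time.
#' @param outDir Output directory.
#' @param minExonIdentity Segmentation identity threshold.
#' @param chimeraMinSegment,chimeraMaxMismatch,chimeraMargin Chimera
#'   detector parameters (see [detectChimeras()]).
#' @param patchWindow,patchThreshold Patch detector parameters (see
#'   [findPatches()]).
#' @param accounting Silent/replacement accounting switch (see
#'   [compareRegions()]).
#' @return A validated list of class `"RunConfig"`.
#' @export
pipelineConfig <- function(simulation = NULL,
                           clonesFasta = NULL, clonesTsv = NULL,
                           modelsJson = NULL,
                           outDir = tempfile("bgrun"),
                           minExonIdentity = 0.85,
                           chimeraMinSegment = 150L,
                           chimeraMaxMismatch = 2L,
                           chimeraMargin = 3L,
                           patchWindow = 4L,
                           patchThreshold = 0.6,
                           accounting = "per_position") {
  if (is.null(simulation)) {
    for (p in c(clonesFasta, modelsJson))
      if (is.null(p) || !file.exists(p))
        stop("validation error: input path missing or not found: ",
             if (is.null(p)) "(NULL)" else p, call. = FALSE)
    if (!is.null(clonesTsv) && !file.exists(clonesTsv))
      stop("validation error: input path missing or not found: ", clonesTsv,
           call. = FALSE)
  } else stopifnot(inherits(simulation, "SimulationConfig"))
  structure(list(
    simulation = simulation, clonesFasta = clonesFasta,
    clonesTsv = clonesTsv, modelsJson = modelsJson, outDir = outDir,
    minExonIdentity = minExonIdentity,
    chimeraMinSegment = as.integer(chimeraMinSegment),
    chimeraMaxMismatch = as.integer(chimeraMaxMismatch),
    chimeraMargin = as.integer(chimeraMargin),
    patchWindow = as.integer(patchWindow),
    patchThreshold = patchThreshold,
    accounting = accounting), class = "RunConfig")
}

.writeTsv <- function(x, path)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the full BG clone-analysis pipeline
#'
#' Executes simulate (or load) -> annotate -> group -> chimera/singleton
#' screening -> naming -> coiled-coil analysis -> region comparison, writing
#' per-stage TSV/JSON outputs and a summary report to `config$outDir`.
#' Given identical config (including seed) the TSV/JSON outputs are
#' byte-identical; wall-clock timings go to `log.txt` only.
#'
#' @param config A [pipelineConfig()].
#' @return The report, invisibly (also written as `report.json`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(config$outDir, "log.txt")
  t0 <- Sys.time()
  logLine <- function(...) cat(..., "\n", sep = "",
                               file = logPath, append = TRUE)
  cat("", file = logPath)
  logLine("bgalleles ", as.character(utils::packageVersion("bgalleles")))
  cfgSerial <- unclass(config)
  if (!is.null(cfgSerial$simulation))
    cfgSerial$simulation <- unclass(cfgSerial$simulation)
  ser <- jsonlite::toJSON(cfgSerial, auto_unbox = TRUE, digits = NA,
                          null = "null")
  writeLines(ser, file.path(config$outDir, "config.json"))
  logLine("config hash ", sprintf("%08x", sum(utf8ToInt(as.character(ser)))))
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    logLine(sprintf("stage %-10s %.2fs", name,
                    as.numeric(Sys.time() - ts, units = "secs")))
    out
  }
  # --- inputs ---
  inputs <- stage("input", {
    if (!is.null(config$simulation)) {
      fam <- simulateGeneFamily(config$simulation)
      libres <- simulateCloneLibrary(fam$genes, config$simulation)
      writeGeneModel(fam$genes, file.path(config$outDir, "models.json"))
      writeCloneLibrary(libres$library, config$outDir)
      .writeTsv(libres$truth, file.path(config$outDir, "truth.tsv"))
      list(models = fam$genes, lib = libres$library, truth = libres$truth)
    } else {
      models <- loadGeneModel(config$modelsJson, "json")
      if (methods::is(models, "GeneModel")) models <- list(models)
      list(models = models,
           lib = readCloneLibrary(config$clonesFasta, config$clonesTsv),
           truth = NULL)
    }
  })
  anns <- stage("annotate", {
    a <- annotateLibrary(inputs$lib, inputs$models, config$minExonIdentity)
    .writeTsv(annotationSummary(a), file.path(config$outDir, "annotations.tsv"))
    a
  })
  grouped <- stage("group", {
    g <- suppressWarnings(groupByExon2(anns, cloneMeta(inputs$lib)))
    g <- flagSingletons(g)
    g
  })
  screened <- stage("chimeras", {
    calls <- detectChimeras(anns, grouped,
                            config$chimeraMinSegment,
                            config$chimeraMaxMismatch,
                            config$chimeraMargin)
    jsonlite::write_json(calls, file.path(config$outDir, "chimeras.json"),
                         dataframe = "rows", pretty = TRUE, digits = NA)
    if (nrow(calls)) {
      keep <- !vapply(anns, function(a) a@cloneId %in% calls$clone_id,
                      logical(1L))
      removedEx2 <- vapply(anns[!keep], .exon2Of, character(1L))
      g2 <- suppressWarnings(groupByExon2(anns[keep], cloneMeta(inputs$lib)))
      g2 <- flagSingletons(g2)
      for (i in seq_along(g2))
        if (g2[[i]]@exon2Seq %in% removedEx2)
          g2[[i]]@flags <- union(g2[[i]]@flags, "chimeric_members_removed")
      list(groups = g2, anns = anns[keep], calls = calls)
    } else list(groups = grouped, anns = anns, calls = calls)
  })
  groups <- screened$groups
  names <- stage("name", {
    nm <- nameSequences(groups)
    .writeTsv(data.frame(clone_id = names(nm), name = unname(nm)),
              file.path(config$outDir, "names.tsv"))
    nm
  })
  groupsTsv <- do.call(rbind, lapply(groups, function(g) data.frame(
    line = g@line, letter = g@letter,
    n_clones = groupCloneCount(g), n_variants = nrow(g@variants),
    flags = paste(g@flags, collapse = ","),
    exon2_nt = nchar(g@exon2Seq), stringsAsFactors = FALSE)))
  .writeTsv(groupsTsv, file.path(config$outDir, "groups.tsv"))
  annById <- stats::setNames(screened$anns,
                             vapply(screened$anns, function(a) a@cloneId,
                                    character(1L)))
  # --- coiled-coil analysis of each line's dominant gene ---
  coil <- stage("coil", {
    out <- list()
    for (ln in unique(vapply(groups, function(g) g@line, character(1L)))) {
      dom <- Filter(function(g) g@line == ln && g@letter == "a", groups)[[1L]]
      ann <- annById[[dom@variants$representative[1L]]]
      tab <- tailRegisterTable(ann)
      nm <- sprintf("%sTBGa", ln)
      .writeTsv(tab, file.path(config$outDir,
                               sprintf("register_%s.tsv", nm)))
      out[[nm]] <- list(
        table = tab,
        hydrophobicity = interfaceHydrophobicity(tab),
        patches = findPatches(tab, config$patchWindow, config$patchThreshold))
    }
    jsonlite::write_json(
      lapply(out, function(x) x$patches),
      file.path(config$outDir, "patches.json"),
      dataframe = "rows", pretty = TRUE, digits = NA)
    out
  })
  variation <- stage("compare", {
    # reference: the first line's dominant gene; compared against the other
    # lines' dominants or, in a single-line run, the subdominant genes
    doms <- Filter(function(g) g@letter == "a", groups)
    others <- if (length(doms) >= 2L) doms[-1L] else
      Filter(function(g) g@letter != "a", groups)
    others <- utils::head(others, 8L)
    if (length(others) >= 1L) {
      refAnn <- annById[[doms[[1L]]@variants$representative[1L]]]
      comps <- lapply(others, function(g)
        compareRegions(refAnn, annById[[g@variants$representative[1L]]],
                       accounting = config$accounting))
      .writeTsv(do.call(rbind, comps),
                file.path(config$outDir, "comparisons.tsv"))
      sel <- selectionSummary(comps)
      jsonlite::write_json(sel, file.path(config$outDir, "selection.json"),
                           dataframe = "rows", pretty = TRUE, digits = NA)
      list(comparisons = comps, selection = sel)
    } else NULL
  })
  # --- report ---
  lines <- vapply(groups, function(g) g@line, character(1L))
  report <- list(
    n_clones = length(anns),
    n_unassignable = sum(vapply(anns, function(a) a@unassignable, logical(1L))),
    n_chimeras = nrow(screened$calls),
    genes_per_line = lapply(split(groups, lines), length),
    dominant_per_line = lapply(split(groups, lines), function(gs) {
      dom <- Filter(function(g) g@letter == "a", gs)[[1L]]
      list(name = paste0(dom@line, "TBGa"),
           n_clones = groupCloneCount(dom),
           n_splice_variants = nrow(dom@variants))
    }),
    flagged_misincorporation = vapply(
      Filter(function(g) "possible_misincorporation" %in% g@flags, groups),
      function(g) paste0(g@line, "TBG", g@letter), character(1L)))
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logLine(sprintf("total %.2fs", as.numeric(Sys.time() - t0, units = "secs")))
  invisible(list(report = report, groups = groups, annotations = screened$anns,
                 chimeras = screened$calls, coil = coil,
                 variation = variation, truth = inputs$truth))
}

#' Summary table of a list of annotations
#'
#' @param annotations List of [TranscriptAnnotation].
#' @return `data.frame`: clone id, model, retained-intron count, tail length
#'   (aa, actual transcript) and apparent heptads (conceptual and actual).
#' @export
annotationSummary <- function(annotations) {
  do.call(rbind, lapply(annotations, function(a) data.frame(
    clone_id = a@cloneId,
    model = if (a@unassignable) NA_character_ else a@modelName,
    unassignable = a@unassignable,
    n_retained_introns = length(a@retainedIntrons),
    tail_length_aa = a@tailLengthAa,
    heptads_conceptual = if (a@unassignable) NA_integer_ else
      as.integer(countApparentHeptads(a, "conceptual")),
    heptads_actual = if (a@unassignable) NA_integer_ else
      as.integer(countApparentHeptads(a, "actual")),
    stringsAsFactors = FALSE)))
}

# ---- GenBank accessions ---------------------------------------------------

#' Parse a BG transcript name into its components
#'
#' Names follow `{line}TBG{letter}[-{variant}]`, e.g. `NTBGa-1` (line N,
#' T cells, exon-2 sequence "a", splice variant 1) or `6TBGd` (letter-only:
#' seen only with a different primer set).
#'
#' @param name Character vector of names.
#' @return `data.frame` with columns `name`, `line`, `letter`, `variant`.
#' @export
parseCloneName <- function(name) {
  m <- regexec("^(.*?)TBG([a-z]+)(?:-([0-9]+))?$", name)
  parts <- regmatches(name, m)
  do.call(rbind, lapply(seq_along(name), function(i) {
    p <- parts[[i]]
    if (length(p) == 0L)
      return(data.frame(name = name[i], line = NA_character_,
                        letter = NA_character_, variant = NA_integer_,
                        stringsAsFactors = FALSE))
    data.frame(name = name[i], line = p[2L], letter = p[3L],
               variant = if (nzchar(p[4L])) as.integer(p[4L]) else NA_integer_,
               stringsAsFactors = FALSE)
  }))
}

#' Fetch deposited clone sequences from GenBank (with local cache)
#'
#' Downloads nucleotide records as FASTA via NCBI efetch and caches each
#' one under `cacheDir`; cached records are reused without network access,
#' so a previously populated cache works fully offline. Records are
#' converted to the package's clone convention, parsing the chicken line
#' from the transcript name in the definition line when present.
#'
#' @param ids Character vector of accessions (e.g. `"MH156615"`).
#' @param cacheDir Cache directory (created if needed).
#' @return A [CloneLibrary].
#' @export
fetchAccessions <- function(ids,
                            cacheDir = tools::R_user_dir("bgalleles", "cache")) {
  bad <- !grepl("^[A-Z]{1,2}[0-9]{5,8}(\\.[0-9]+)?$", ids)
  if (any(bad))
    stop("malformed accession(s): ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(cacheDir, paste0(ids, ".fasta"))
  missing <- !file.exists(paths)
  if (any(missing)) {
    url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                  "?db=nuccore&rettype=fasta&retmode=text&id=")
    for (i in which(missing)) {
      ok <- tryCatch({
        utils::download.file(paste0(url, ids[i]), paths[i], quiet = TRUE)
        TRUE
      }, error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok && file.exists(paths[i])) file.remove(paths[i])
    }
    still <- !file.exists(paths)
    if (any(still))
      stop("could not fetch accession(s) (network failure and no cached ",
           "copy): ", paste(ids[still], collapse = ", "), call. = FALSE)
  }
  seqs <- do.call(c, lapply(paths, Biostrings::readDNAStringSet))
  # prefer the transcript name (e.g. NTBGa-1) from the defline when present
  defl <- names(seqs)
  nm <- regmatches(defl, regexpr("[A-Za-z0-9]+TBG[a-z]+(-[0-9]+)?", defl))
  cloneIds <- if (length(nm) == length(seqs) && !anyNA(nm)) nm else
    sub("[ .].*$", "", defl)
  names(seqs) <- make.unique(cloneIds)
  info <- parseCloneName(names(seqs))
  CloneLibrary(seqs, data.frame(
    clone_id = names(seqs),
    line = ifelse(is.na(info$line), "?", info$line),
    pcr_batch = "GenBank", n_observed = 1L, stringsAsFactors = FALSE))
}
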