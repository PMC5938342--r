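#' @importFrom Biostrings pairwiseAlignment nmatch matchPattern
NULL

.nucMat <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE)
    cache
  }
})

# Semi-global location of `target` within clone[p..], allowing a preceding
# gap of up to `gapAllow` nt. Exact substring checks first (the common case
# for Sanger-finished clones), banded alignment as fallback.
# Returns NULL or list(start, end, identity, gapStart, gapEnd).
.locateSegment <- function(cloneStr, target, p, gapAllow, minId) {
  L <- nchar(cloneStr)
  w <- nchar(target)
  if (p > L) return(NULL)
  # fast path: exact at p
  if (p + w - 1L <= L && substr(cloneStr, p, p + w - 1L) == target)
    return(list(start = p, end = p + w - 1L, identity = 1,
                gapStart = NA, gapEnd = NA))
  # fast path: exact after a gap (e.g. a retained intron)
  if (gapAllow > 0L) {
    hitEnd <- min(L, p + gapAllow + w + 30L)
    win <- substr(cloneStr, p, hitEnd)
    off <- regexpr(target, win, fixed = TRUE)[1L]
    if (off > 0L) {
      s <- p + off - 1L
      return(list(start = s, end = s + w - 1L, identity = 1,
                  gapStart = if (off > 1L) p else NA,
                  gapEnd = if (off > 1L) s - 1L else NA))
    }
  }
  winEnd <- min(L, p + gapAllow + w + 30L)
  if (winEnd - p + 1L < max(10L, w %/% 2L)) return(NULL)
  win <- substr(cloneStr, p, winEnd)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(target), Biostrings::DNAString(win),
    type = "global-local", substitutionMatrix = .nucMat(),
    gapOpening = 4, gapExtension = 1)
  id <- Biostrings::nmatch(aln) / w
  if (id < minId) return(NULL)
  s <- p + IRanges::start(Biostrings::subject(aln)@range) - 1L
  e <- p + IRanges::end(Biostrings::subject(aln)@range) - 1L
  list(start = s, end = e, identity = id,
       gapStart = if (s > p) p else NA, gapEnd = if (s > p) s - 1L else NA)
}

# Classify the clone gap [gs, ge] against a model intron sequence.
.classifyGap <- function(cloneStr, gs, ge, intronSeq, minId) {
  gap <- substr(cloneStr, gs, ge)
  if (nzchar(intronSeq)) {
    if (gap == intronSeq) return(list(kind = "retained_intron", identity = 1))
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(gap), Biostrings::DNAString(intronSeq),
      type = "global", substitutionMatrix = .nucMat(),
      gapOpening = 4, gapExtension = 1)
    id <- Biostrings::nmatch(aln) / max(nchar(gap), nchar(intronSeq))
    if (id >= minId) return(list(kind = "retained_intron", identity = id))
  }
  list(kind = "unaligned", identity = 0)
}

# Segment one clone against one model. Returns list(segments, score,
# extraRepeats, nLocated).
.segmentAgainstModel <- function(cloneStr, model, minId, maxExtraRepeats = 12L) {
  exSeqs <- .exonSeqs(model)
  inSeqs <- .intronSeqs(model)
  kinds <- .exonKinds(model)
  n <- length(exSeqs)
  segs <- list()
  addSeg <- function(start, end, label, kind, exonIndex, identity)
    segs[[length(segs) + 1L]] <<- data.frame(
      start = start, end = end, label = label, kind = kind,
      exonIndex = exonIndex, identity = identity, stringsAsFactors = FALSE)
  p <- 1L
  matchedNt <- 0
  nLocated <- 0L
  extras <- 0L
  placeExon <- function(i, target, label) {
    gapAllow <- if (p > 1L && i >= 2L)
      nchar(inSeqs[min(i - 1L, length(inSeqs))]) + 60L else 60L
    hit <- .locateSegment(cloneStr, target, p, gapAllow, minId)
    if (is.null(hit)) return(FALSE)
    if (!is.na(hit$gapStart)) {
      intr <- if (i >= 2L) inSeqs[min(i - 1L, length(inSeqs))] else ""
      cls <- .classifyGap(cloneStr, hit$gapStart, hit$gapEnd, intr, minId)
      addSeg(hit$gapStart, hit$gapEnd,
             if (cls$kind == "retained_intron")
               sprintf("retained-intron after exon %d", i - 1L)
             else "unaligned",
             cls$kind, if (cls$kind == "retained_intron") i - 1L else NA_integer_,
             cls$identity)
    }
    addSeg(hit$start, hit$end, label, "exon", i, hit$identity)
    matchedNt <<- matchedNt + hit$identity * nchar(target)
    nLocated <<- nLocated + 1L
    p <<- hit$end + 1L
    TRUE
  }
  for (i in seq_len(n)) {
    placed <- placeExon(i, exSeqs[i], sprintf("exon %d", i))
    if (!placed || kinds[i] != "repeat") next
    # after a repeat exon, greedily consume extra tandem copies of it
    # (clones can carry duplicated repeat-exon cassettes absent from the
    # model); the model's own next exon is preferred when it explains the
    # same stretch at least as well
    while (extras < maxExtraRepeats) {
      gapAllow <- nchar(inSeqs[i]) + 60L
      hit <- .locateSegment(cloneStr, exSeqs[i], p, gapAllow, minId)
      if (is.null(hit)) break
      if (i < n) {
        nxt <- .locateSegment(cloneStr, exSeqs[i + 1L], p, gapAllow, minId)
        if (!is.null(nxt) && nxt$identity >= hit$identity &&
            nxt$start <= hit$start) break
      }
      if (!is.na(hit$gapStart)) {
        cls <- .classifyGap(cloneStr, hit$gapStart, hit$gapEnd,
                            inSeqs[i], minId)
        if (cls$kind != "retained_intron") break
        addSeg(hit$gapStart, hit$gapEnd,
               sprintf("retained-intron after exon %d", i),
               "retained_intron", i, cls$identity)
      }
      extras <- extras + 1L
      addSeg(hit$start, hit$end,
             sprintf("extra repeat %d", extras), "exon", i, hit$identity)
      matchedNt <- matchedNt + hit$identity * nchar(exSeqs[i])
      nLocated <- nLocated + 1L
      p <- hit$end + 1L
    }
  }
  L <- nchar(cloneStr)
  if (p <= L)
    addSeg(p, L, "unaligned", "unaligned", NA_integer_, 0)
  segdf <- if (length(segs)) do.call(rbind, segs) else
    data.frame(start = integer(), end = integer(), label = character(),
               kind = character(), exonIndex = integer(), identity = numeric())
  list(segments = segdf, score = matchedNt / sum(nchar(exSeqs)),
       extraRepeats = extras, nLocated = nLocated)
}

#' Segment a cDNA clone against gene models
#'
#' Locates each model exon in the clone by exact search and semi-global
#' alignment, in model order; clone stretches between consecutive located
#' exons that match the model's intervening intron are labelled retained
#' introns, other stretches unaligned. Among several models, the one
#' maximising total aligned identity wins. Clones in which no exon reaches
#' `minExonIdentity` are returned flagged `unassignable` rather than
#' raising an error. Extra tandem repeat-exon copies beyond the model's
#' inventory are tolerated and reported.
#'
#' @param clone Clone sequence (character or [Biostrings::DNAString]),
#'   at least 200 nt.
#' @param models A [GeneModel] or list of them.
#' @param minExonIdentity Minimum per-exon identity fraction (default 0.85,
#'   tolerant of inter-haplotype divergence while rejecting random
#'   sequence).
#' @param cloneId Identifier carried into the result.
#' @return List with elements `cloneId`, `bestModel`, `segments`
#'   (`data.frame`), `score`, `extraRepeats`, `unassignable`.
#' @seealso [annotateClone()] for the full annotation including translation.
#' @export
segmentClone <- function(clone, models, minExonIdentity = 0.85,
                         cloneId = "clone") {
  if (methods::is(models, "GeneModel")) models <- list(models)
  if (length(models) == 0L) stop("need at least one model", call. = FALSE)
  cloneStr <- toupper(as.character(clone))
  if (nchar(cloneStr) < 200L)
    stop("clone must be at least 200 nt", call. = FALSE)
  # screen: models whose exon-2 occurs exactly in the clone are tried first
  ex2 <- vapply(models, function(m) {
    k <- which(.exonKinds(m) == "igv")
    .exonSeqs(m)[k]
  }, character(1L))
  hasEx2 <- vapply(ex2, function(s)
    grepl(s, cloneStr, fixed = TRUE), logical(1L))
  ord <- order(!hasEx2)
  best <- NULL; bestScore <- -Inf; bestName <- NA_character_
  for (mi in ord) {
    res <- .segmentAgainstModel(cloneStr, models[[mi]], minExonIdentity)
    if (res$score > bestScore) {
      best <- res; bestScore <- res$score
      bestName <- modelName(models[[mi]])
    }
    if (res$score >= 0.999) break
  }
  list(cloneId = cloneId, bestModel = bestName, segments = best$segments,
       score = bestScore, extraRepeats = best$extraRepeats,
       unassignable = best$nLocated == 0L)
}

# ---- translation with split codons ---------------------------------------

#' Translate a segmented clone in the signal-sequence frame
#'
#' Concatenates the coding parts of the located segments (from the
#' signal-sequence ATG onwards), optionally including retained introns,
#' and translates with the standard genetic code, halting at the first
#' in-frame stop. Because repeat exons are phase 1, boundary codons are
#' split across exons; each codon is attributed to the segment contributing
#' two of its three nucleotides, which drives the heptad-register and
#' split-codon accounting downstream.
#'
#' @param clone Clone sequence.
#' @param segments Segment table from [segmentClone()].
#' @param model The matching [GeneModel].
#' @param useRetained Include retained-intron segments in the reading frame
#'   (the "actual" transcript) instead of skipping them (the "conceptual"
#'   transcript).
#' @return List with `cds` (character), `protein` (character, up to the
#'   stop), `stopPosition` (`list(label, offset)` of the stop codon's first
#'   nucleotide in segment coordinates, or `NULL`), and `codons`
#'   (per-codon provenance `data.frame`).
#' @export
translateWithSplitCodons <- function(clone, segments, model,
                                     useRetained = FALSE) {
  cloneStr <- toupper(as.character(clone))
  segs <- segments[order(segments$start), , drop = FALSE]
  e1 <- which(segs$kind == "exon" & segs$exonIndex == 1L)
  if (length(e1) != 1L)
    stop("signal start not located", call. = FALSE)
  codingStart <- segs$start[e1] + model@utr5Length
  if (codingStart > segs$end[e1])
    stop("signal start not located", call. = FALSE)
  keep <- segs$kind == "exon" | (useRetained & segs$kind == "retained_intron")
  segs <- segs[keep, , drop = FALSE]
  # clone positions entering the reading frame, with their segment of origin
  posList <- list(); segOf <- list()
  for (r in seq_len(nrow(segs))) {
    s <- max(segs$start[r], codingStart)
    if (s > segs$end[r]) next
    idx <- s:segs$end[r]
    posList[[length(posList) + 1L]] <- idx
    segOf[[length(segOf) + 1L]] <- rep(r, length(idx))
  }
  pos <- unlist(posList); segOf <- unlist(segOf)
  cloneChars <- strsplit(cloneStr, "")[[1]]
  cds <- paste(cloneChars[pos], collapse = "")
  nCodon <- length(pos) %/% 3L
  if (nCodon == 0L) stop("signal start not located", call. = FALSE)
  codonStr <- substring(cds, 3L * seq_len(nCodon) - 2L, 3L * seq_len(nCodon))
  aas <- .translateCodons(codonStr)
  stopIdx <- which(aas == "*")[1L]
  if (is.na(stopIdx) && length(pos) %% 3L != 0L)
    warning("CDS length not a multiple of 3; ignoring trailing ",
            length(pos) %% 3L, " nt")
  protein <- paste(aas[seq_len(if (is.na(stopIdx)) nCodon else stopIdx - 1L)],
                   collapse = "")
  # per-codon provenance: owning segment = the one contributing >= 2 nt.
  # Segments are contiguous, so a codon spans at most two of them and the
  # majority owner is decided by the first two / last two positions.
  s1 <- segOf[3L * seq_len(nCodon) - 2L]
  s2 <- segOf[3L * seq_len(nCodon) - 1L]
  s3 <- segOf[3L * seq_len(nCodon)]
  ownSeg <- ifelse(s1 == s2, s1, s2)  # s2 == s3 whenever s1 != s2
  kinds <- .exonKinds(model)
  segExon <- segs$exonIndex
  segKind <- segs$kind
  isExtra <- grepl("^extra repeat", segs$label)
  # per-segment attributes
  segIsRep <- segKind == "exon" & (kinds[segExon] == "repeat" | isExtra)
  segRepRank <- cumsum(segIsRep)
  nRepSegs <- sum(segIsRep)
  segRegion <- ifelse(segKind == "retained_intron", "retained_intron",
    vapply(seq_len(nrow(segs)), function(r) {
      k <- kinds[segExon[r]]
      if (isExtra[r]) k <- "repeat"
      switch(k, utr5_signal = "signal", igv = "igv", tm = "tm",
             "repeat" = "tail", final = "final_exon")
    }, character(1L)))
  exonIndexOf <- segExon[ownSeg]
  region <- segRegion[ownSeg]
  # running codon count within each owning segment
  perSegCount <- stats::ave(seq_len(nCodon), ownSeg, FUN = seq_along)
  unitIndex <- rep(NA_integer_, nCodon)
  codonPos <- rep(NA_integer_, nCodon)
  isTail <- region == "tail"
  unitIndex[isTail] <- segRepRank[ownSeg[isTail]]
  codonPos[isTail] <- perSegCount[isTail]
  isFinal <- region == "final_exon"
  unitIndex[isFinal] <- nRepSegs + (perSegCount[isFinal] - 1L) %/% 7L + 1L
  codonPos[isFinal] <- (perSegCount[isFinal] - 1L) %% 7L + 1L
  translated <- seq_len(nCodon) < if (is.na(stopIdx)) nCodon + 1L else stopIdx
  codons <- data.frame(
    codon = codonStr, aa = aas, exonIndex = exonIndexOf, region = region,
    unitIndex = unitIndex, codonPos = codonPos, translated = translated,
    segRow = ownSeg, stringsAsFactors = FALSE)
  stopPosition <- NULL
  if (!is.na(stopIdx)) {
    firstNt <- pos[3L * stopIdx - 2L]
    r <- segOf[3L * stopIdx - 2L]
    stopPosition <- list(label = segs$label[r],
                         offset = firstNt - segs$start[r] + 1L)
  }
  list(cds = cds, protein = protein, stopPosition = stopPosition,
       codons = codons)
}

# ---- full per-clone annotation -------------------------------------------

#' Annotate a clone end to end
#'
#' Runs [segmentClone()], then [translateWithSplitCodons()] twice (without
#' and with retained introns) and assembles a [TranscriptAnnotation].
#'
#' @inheritParams segmentClone
#' @return A [TranscriptAnnotation].
#' @examples
#' gm <- canonicalGeneModel(nRepeats = 5)
#' tr <- spliceModel(gm)
#' ann <- annotateClone(tr, gm, cloneId = "demo")
#' tailLengthAa(ann)
#' @export
annotateClone <- function(clone, models, minExonIdentity = 0.85,
                          cloneId = "clone") {
  if (methods::is(models, "GeneModel")) models <- list(models)
  seg <- segmentClone(clone, models, minExonIdentity, cloneId)
  cloneStr <- toupper(as.character(clone))
  empty <- function() methods::new("TranscriptAnnotation",
    cloneId = cloneId, modelName = if (is.na(seg$bestModel)) "" else seg$bestModel,
    unassignable = TRUE,
    cloneSeq = Biostrings::DNAString(cloneStr),
    segments = seg$segments,
    conceptualCds = Biostrings::DNAString(""),
    actualCds = Biostrings::DNAString(""),
    proteinConceptual = Biostrings::AAString(""),
    proteinActual = Biostrings::AAString(""),
    stopConceptual = list(), stopActual = list(),
    codonsConceptual = data.frame(), codonsActual = data.frame(),
    retainedIntrons = character(0), tailLengthAa = NA_integer_,
    extraRepeats = 0L)
  if (seg$unassignable) return(empty())
  model <- models[[match(seg$bestModel,
                         vapply(models, modelName, character(1L)))]]
  conc <- tryCatch(
    translateWithSplitCodons(cloneStr, seg$segments, model, useRetained = FALSE),
    error = function(e) NULL)
  if (is.null(conc)) return(empty())
  act <- translateWithSplitCodons(cloneStr, seg$segments, model,
                                  useRetained = TRUE)
  retained <- seg$segments$label[seg$segments$kind == "retained_intron"]
  # translated residues after the TM region on the actual transcript
  tmLast <- max(c(0L, which(act$codons$region == "tm")))
  tailLen <- if (tmLast == 0L) NA_integer_ else
    sum(act$codons$translated[seq_len(nrow(act$codons)) > tmLast])
  methods::new("TranscriptAnnotation",
    cloneId = cloneId, modelName = seg$bestModel, unassignable = FALSE,
    cloneSeq = Biostrings::DNAString(cloneStr),
    segments = seg$segments,
    conceptualCds = Biostrings::DNAString(conc$cds),
    actualCds = Biostrings::DNAString(act$cds),
    proteinConceptual = Biostrings::AAString(conc$protein),
    proteinActual = Biostrings::AAString(act$protein),
    stopConceptual = if (is.null(conc$stopPosition)) list() else conc$stopPosition,
    stopActual = if (is.null(act$stopPosition)) list() else act$stopPosition,
    codonsConceptual = conc$codons,
    codonsActual = act$codons,
    retainedIntrons = retained,
    tailLengthAa = as.integer(tailLen),
    extraRepeats = seg$extraRepeats)
}

#' @rdname annotateClone
#' @param lib A [CloneLibrary].
#' @return For `annotateLibrary`, a named list of [TranscriptAnnotation].
#' @export
annotateLibrary <- function(lib, models, minExonIdentity = 0.85) {
  seqs <- cloneSeqs(lib)
  out <- lapply(seq_along(seqs), function(i)
    annotateClone(seqs[[i]], models, minExonIdentity,
                  cloneId = names(seqs)[i]))
  names(out) <- names(seqs)
  out
}

#' Fully spliced transcript of a gene model
#'
#' Convenience: the conceptual transcript of the model itself (all exons,
#' no introns), as produced by the spliceosome acting on the gene.
#'
#' @param model A [GeneModel].
#' @return Character transcript sequence.
#' @export
spliceModel <- function(model) .spliceTranscript(model)$seq

#' @rdname TranscriptAnnotation-class
#' @export
setMethod("segments", "TranscriptAnnotation", function(x) x@segments)
#' @rdname TranscriptAnnotation-class
#' @export
setMethod("retainedIntrons", "TranscriptAnnotation", function(x) x@retainedIntrons)
#' @rdname TranscriptAnnotation-class
#' @export
setMethod("tailLengthAa", "TranscriptAnnotation", function(x) x@tailLengthAa)

setMethod("show", "TranscriptAnnotation", function(object) {
  cat("TranscriptAnnotation", object@cloneId, "\n")
  if (object@unassignable) {
    cat("  unassignable clone\n"); return(invisible(NULL))
  }
  cat("  best model:", object@modelName,
      " retained introns:", length(object@retainedIntrons),
      " extra repeats:", object@extraRepeats, "\n")
  cat("  conceptual protein:", length(object@proteinConceptual), "aa;",
      "actual protein:", length(object@proteinActual), "aa;",
      "tail:", object@tailLengthAa, "aa\n")
})

setMethod("conceptualTranscript", "TranscriptAnnotation", function(x) {
  segs <- x@segments
  segs <- segs[segs$kind == "exon", , drop = FALSE]
  segs <- segs[order(segs$start), , drop = FALSE]
  cloneStr <- as.character(x@cloneSeq)
  Biostrings::DNAString(paste(substring(cloneStr, segs$start, segs$end),
                              collapse = ""))
})

#' Count apparent heptad repeats in a cytoplasmic tail
#'
#' The number of complete 7-residue repeat units translated after the TM
#' region and before the first stop: each fully translated repeat exon
#' contributes one unit (18/24-nt exons likewise contribute one), plus one
#' for each complete heptad encoded by the final exon before its stop.
#' The stop's location -- in the penultimate exon or at the start of the
#' final exon -- therefore changes the apparent repeat count even between
#' genes with the same exon inventory.
#'
#' @param annotation A [TranscriptAnnotation].
#' @param which Count on the `"conceptual"` (exons only, default) or
#'   `"actual"` (retained introns included) transcript.
#' @return Integer; 0 with attribute `flag = "truncated before tail"` when
#'   the stop precedes the first repeat exon.
#' @examples
#' gm <- canonicalGeneModel(nRepeats = 28, stopHeptads = 1)
#' ann <- annotateClone(spliceModel(gm), gm)
#' countApparentHeptads(ann)  # 29
#' @export
countApparentHeptads <- function(annotation,
                                 which = c("conceptual", "actual")) {
  which <- match.arg(which)
  cod <- if (which == "conceptual") annotation@codonsConceptual
         else annotation@codonsActual
  if (!nrow(cod)) return(0L)
  tail_cod <- cod[cod$region == "tail", , drop = FALSE]
  nFull <- 0L
  if (nrow(tail_cod)) {
    for (u in unique(tail_cod$unitIndex)) {
      uc <- tail_cod[tail_cod$unitIndex == u, , drop = FALSE]
      if (all(uc$translated)) nFull <- nFull + 1L
    }
  }
  finalTranslated <- sum(cod$translated[cod$region == "final_exon"])
  total <- nFull + finalTranslated %/% 7L
  if (total == 0L && !any(tail_cod$translated)) {
    total <- 0L
    attr(total, "flag") <- "truncated before tail"
  }
  total
}
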