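# Letters for gene groups within a line ("a" = most clones).
.groupLetters <- function(n) {
  pool <- c(letters, as.vector(outer(letters, letters, paste0)))
  pool[seq_len(n)]
}

.exon2Of <- function(annotation) {
  segs <- annotation@segments
  r <- which(segs$kind == "exon" & segs$exonIndex == 2L)
  if (length(r) != 1L) return(NA_character_)
  substr(as.character(annotation@cloneSeq), segs$start[r], segs$end[r])
}

#' Collapse annotated clones into putative genes by exon-2 identity
#'
#' Each unique exon-2 (Ig-V) sequence within a chicken line is taken to be
#' one gene; even single-nucleotide exon-2 differences found separate
#' groups, since genuinely distinct BG genes can differ by one nucleotide.
#' Within a line, groups are lettered by descending total clone count
#' ("a" = most frequent) and splice variants within each group -- distinct
#' full clone sequences -- are numbered by descending clone count, ties
#' broken lexicographically by sequence.
#'
#' @param annotations List of [TranscriptAnnotation] (e.g. from
#'   [annotateLibrary()]).
#' @param meta Clone metadata `data.frame` (`clone_id`, `line`,
#'   `pcr_batch`, `n_observed`) or a [CloneLibrary]; defaults are
#'   synthesised when omitted.
#' @param excludeExon2 Optional character vector of reference exon-2
#'   sequences (e.g. of genes outside the study); clones matching one are
#'   dropped before grouping.
#' @return List of [GeneGroup], ordered by line then letter.
#' @export
groupByExon2 <- function(annotations, meta = NULL, excludeExon2 = character(0)) {
  if (methods::is(meta, "CloneLibrary")) meta <- cloneMeta(meta)
  ids <- unname(vapply(annotations, function(a) a@cloneId, character(1L)))
  if (is.null(meta))
    meta <- data.frame(clone_id = ids, line = "?", pcr_batch = "PCR1",
                       n_observed = 1L, stringsAsFactors = FALSE)
  ex2 <- vapply(annotations, .exon2Of, character(1L))
  drop <- is.na(ex2) | vapply(annotations, function(a) a@unassignable, logical(1L))
  if (any(drop))
    warning(sum(drop), " clone(s) lacking a located exon-2 were excluded: ",
            paste(ids[drop], collapse = ", "))
  keepExcl <- !ex2 %in% excludeExon2
  keep <- !drop & keepExcl
  annotations <- annotations[keep]; ids <- ids[keep]; ex2 <- ex2[keep]
  m <- meta[match(ids, meta$clone_id), , drop = FALSE]
  groups <- list()
  for (ln in unique(m$line)) {
    sel <- which(m$line == ln)
    keyTot <- tapply(m$n_observed[sel], ex2[sel], sum)
    ord <- order(-keyTot, names(keyTot))
    seqsOrd <- names(keyTot)[ord]
    lets <- .groupLetters(length(seqsOrd))
    for (gi in seq_along(seqsOrd)) {
      gsel <- sel[ex2[sel] == seqsOrd[gi]]
      fullSeq <- vapply(annotations[gsel], function(a)
        as.character(a@cloneSeq), character(1L))
      vtot <- tapply(m$n_observed[gsel], fullSeq, sum)
      vord <- order(-vtot, names(vtot))
      vseqs <- names(vtot)[vord]
      variants <- do.call(rbind, lapply(seq_along(vseqs), function(vi) {
        vsel <- gsel[fullSeq == vseqs[vi]]
        vids <- sort(ids[match(vsel, seq_along(ids))])
        data.frame(variant = vi,
                   representative = vids[1L],
                   nClones = sum(m$n_observed[vsel]),
                   nBatches = length(unique(m$pcr_batch[vsel])),
                   cloneIdsCsv = paste(vids, collapse = ","),
                   stringsAsFactors = FALSE)
      }))
      flags <- character(0)
      if (length(unique(m$pcr_batch[gsel])) == 1L)
        flags <- c(flags, "single_pcr_only")
      groups[[length(groups) + 1L]] <- methods::new("GeneGroup",
        line = ln, exon2Seq = seqsOrd[gi], letter = lets[gi],
        cloneIds = sort(ids[match(gsel, seq_along(ids))]),
        variants = variants, flags = flags)
    }
  }
  groups
}

#' Total clones in a group
#' @param group A [GeneGroup].
#' @return Integer.
#' @export
groupCloneCount <- function(group) sum(group@variants$nClones)

setMethod("show", "GeneGroup", function(object) {
  cat(sprintf("GeneGroup %sTBG%s: %d clone(s), %d splice variant(s)%s\n",
              object@line, object@letter, groupCloneCount(object),
              nrow(object@variants),
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ","), "]")
              else ""))
})

#' Flag groups likely caused by PCR mis-incorporation
#'
#' A group is flagged `possible_misincorporation` when it holds exactly one
#' clone, was seen in exactly one PCR batch, and its exon-2 differs by
#' exactly one nucleotide from a larger group in the same line. Flagged
#' groups are retained, not removed: separate genes with single-nucleotide
#' exon-2 differences genuinely exist.
#'
#' @param groups List of [GeneGroup] from [groupByExon2()].
#' @return The list with flags updated.
#' @export
flagSingletons <- function(groups) {
  lines <- vapply(groups, function(g) g@line, character(1L))
  tot <- vapply(groups, groupCloneCount, numeric(1L))
  oneBatch <- vapply(groups, function(g) {
    "single_pcr_only" %in% g@flags
  }, logical(1L))
  for (i in seq_along(groups)) {
    if (tot[i] != 1L || !oneBatch[i]) next
    ex2 <- groups[[i]]@exon2Seq
    bigger <- which(lines == lines[i] & tot > tot[i])
    hit <- any(vapply(bigger, function(j) {
      o <- groups[[j]]@exon2Seq
      nchar(o) == nchar(ex2) && .hamming(o, ex2) == 1L
    }, logical(1L)))
    if (hit)
      groups[[i]]@flags <- union(groups[[i]]@flags, "possible_misincorporation")
  }
  groups
}

# Per-position mismatch profile of clone string c against parent string p,
# on c's coordinates. Positions of c inserted relative to p count as
# mismatches; deletions in c do not occupy c positions.
.mismatchProfile <- function(c, p) {
  if (nchar(c) == nchar(p)) {
    return(strsplit(c, "")[[1]] != strsplit(p, "")[[1]])
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(c), Biostrings::DNAString(p),
    type = "global", substitutionMatrix = .nucMat(),
    gapOpening = 4, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- pa != "-"
  (pa != sa)[keep]
}

#' Detect PCR chimeras by single-crossover testing
#'
#' For every clone, asks whether a two-parent explanation -- a prefix
#' matching one gene group's representative and a suffix matching
#' another's, switching once -- beats every single-parent explanation by at
#' least `margin` mismatches, with each side at least `minSegment` nt long
#' and carrying at most `maxMismatch` mismatches. Comparison is on
#' conceptual transcripts. The reported breakpoint window spans the
#' informative sites bracketing the inferred switch.
#'
#' @param annotations List of [TranscriptAnnotation].
#' @param groups List of [GeneGroup] (need at least two).
#' @param minSegment Minimum parent segment length (nt, default 150).
#' @param maxMismatch Maximum mismatches tolerated per side (default 2).
#' @param margin Required advantage (mismatches) of the two-parent over the
#'   best single-parent explanation (default 3).
#' @return `data.frame` of chimera calls: `clone_id`, `parent_a`,
#'   `parent_b`, `bp_start`, `bp_end`, `mm_two_parent`, `mm_single`.
#' @export
detectChimeras <- function(annotations, groups, minSegment = 150L,
                           maxMismatch = 2L, margin = 3L) {
  emptyCalls <- data.frame(clone_id = character(), parent_a = character(),
                           parent_b = character(), bp_start = integer(),
                           bp_end = integer(), mm_two_parent = integer(),
                           mm_single = integer(), stringsAsFactors = FALSE)
  if (length(groups) < 2L) return(emptyCalls)
  annById <- stats::setNames(annotations,
                             vapply(annotations, function(a) a@cloneId,
                                    character(1L)))
  ctCache <- new.env(parent = emptyenv())
  ctOf <- function(id) {
    if (is.null(ctCache[[id]]))
      ctCache[[id]] <- as.character(conceptualTranscript(annById[[id]]))
    ctCache[[id]]
  }
  # parent representative for a group, never the clone under test itself:
  # fall back to the next member (conceptual transcripts within a group
  # differ only by retained introns, so any member is equivalent)
  repFor <- function(g, excludeId) {
    ids <- unlist(strsplit(g@variants$cloneIdsCsv, ","))
    ids <- ids[ids != excludeId]
    if (length(ids)) ids[1L] else NA_character_
  }
  pnames <- vapply(groups, function(g)
    paste0(g@line, "TBG", g@letter), character(1L))
  calls <- list()
  for (a in annotations) {
    if (a@unassignable) next
    cs <- ctOf(a@cloneId)
    L <- nchar(cs)
    repIds <- vapply(groups, repFor, character(1L), excludeId = a@cloneId)
    usable <- which(!is.na(repIds))
    if (length(usable) < 2L) next
    # equal-length parents compare by cheap column comparison; if one
    # explains the clone perfectly there is nothing to test, and the
    # expensive alignments against unequal-length parents are skipped
    pseqs <- lapply(repIds[usable], ctOf)
    sameLen <- vapply(pseqs, nchar, integer(1L)) == L
    if (any(sameLen)) {
      quick <- vapply(pseqs[sameLen], function(p)
        sum(strsplit(cs, "")[[1]] != strsplit(p, "")[[1]]), numeric(1L))
      if (min(quick) == 0) next
    }
    profiles <- lapply(pseqs, .mismatchProfile, c = cs)
    singles <- vapply(profiles, sum, numeric(1L))
    bestSingle <- min(singles)
    if (bestSingle == 0) next
    best <- NULL
    for (i in seq_along(profiles)) for (j in seq_along(profiles)) {
      if (i == j) next
      cumA <- cumsum(profiles[[i]])
      cumB <- cumsum(profiles[[j]])
      SB <- cumB[L]
      bps <- seq.int(minSegment, L - minSegment)
      if (!length(bps)) next
      left <- cumA[bps]
      right <- SB - cumB[bps]
      ok <- left <= maxMismatch & right <= maxMismatch
      if (!any(ok)) next
      tot <- left + right
      tot[!ok] <- Inf
      bp <- bps[which.min(tot)]
      if (is.null(best) || min(tot) < best$mm) {
        best <- list(i = i, j = j, bp = bp, mm = min(tot),
                     mA = profiles[[i]], mB = profiles[[j]])
      }
    }
    if (is.null(best) || best$mm > bestSingle - margin) next
    # informative interval bracketing the switch
    infL <- which(!best$mA & best$mB)          # clone follows parent A here
    infR <- which(best$mA & !best$mB)          # clone follows parent B here
    bpS <- suppressWarnings(max(infL[infL <= best$bp]))
    bpE <- suppressWarnings(min(infR[infR > best$bp]))
    if (!is.finite(bpS)) bpS <- best$bp
    if (!is.finite(bpE)) bpE <- best$bp
    calls[[length(calls) + 1L]] <- data.frame(
      clone_id = a@cloneId,
      parent_a = pnames[usable[best$i]], parent_b = pnames[usable[best$j]],
      bp_start = as.integer(bpS), bp_end = as.integer(bpE),
      mm_two_parent = as.integer(best$mm),
      mm_single = as.integer(bestSingle), stringsAsFactors = FALSE)
  }
  if (!length(calls)) return(emptyCalls)
  do.call(rbind, calls)
}

#' Name clones by the line/letter/variant convention
#'
#' Builds names of the form `{line}TBG{letter}-{variant}` (for example
#' `NTBGa-1`: line N, T cells, most frequent exon-2 sequence, most frequent
#' splice variant). Groups flagged `letter_only` (e.g. detected only by a
#' different primer set) receive a letter-only name without a variant
#' number.
#'
#' @param groups List of [GeneGroup].
#' @param lineAbbrev Optional override of each group's line abbreviation.
#' @return Named character vector mapping clone id to name (clones sharing
#'   a splice variant share its name).
#' @export
nameSequences <- function(groups, lineAbbrev = NULL) {
  out <- character(0)
  seen <- character(0)
  for (g in groups) {
    ln <- if (is.null(lineAbbrev)) g@line else lineAbbrev
    if ("letter_only" %in% g@flags) {
      nm <- sprintf("%sTBG%s", ln, g@letter)
      ids <- g@cloneIds
      out[ids] <- nm
      seen <- c(seen, nm)
      next
    }
    for (vi in seq_len(nrow(g@variants))) {
      nm <- sprintf("%sTBG%s-%d", ln, g@letter, g@variants$variant[vi])
      if (nm %in% seen)
        stop("internal error: duplicate name ", nm, call. = FALSE)
      seen <- c(seen, nm)
      ids <- strsplit(g@variants$cloneIdsCsv[vi], ",")[[1]]
      out[ids] <- nm
    }
  }
  out
}
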