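# Region-wise silent/replacement comparison of conceptual transcripts.
#
# Coding regions are compared codon-wise; every codon is attributed to the
# region of the exon contributing two of its three nucleotides, so the
# boundary-split codon at the signal/Ig-V junction is counted in the Ig-V
# domain (the published convention). utr5 and the untranslated remainder of
# the final exon are compared nucleotide-wise.

.codingRegions <- c("signal", "igv", "tm", "tail", "final_exon")

# Split the conceptual codon table into per-region codon vectors; tail
# codons keep their repeat-unit structure.
.codonsByRegion <- function(ann) {
  cod <- ann@codonsConceptual
  cod <- cod[cod$translated, , drop = FALSE]
  lapply(stats::setNames(nm = .codingRegions), function(r)
    cod[cod$region == r, , drop = FALSE])
}

.utr5Of <- function(ann) {
  L <- length(conceptualTranscript(ann))
  cdsLen <- length(ann@conceptualCds)
  substr(as.character(conceptualTranscript(ann)), 1L, L - cdsLen)
}

.posDiff <- function(a, b) which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

#' Classify a codon change as silent or replacement
#'
#' Whole-codon comparison under the standard genetic code: a change is
#' silent when both codons encode the same amino acid and replacement
#' otherwise, regardless of how many of the three nucleotides changed.
#'
#' @param ref,alt Three-letter codons.
#' @return `"none"` (identical codons), `"silent"` or `"replacement"`.
#' @examples
#' classifyCodonChange("GCA", "GCC")  # silent (Ala/Ala)
#' classifyCodonChange("AAA", "GAA")  # replacement (K -> E)
#' @export
classifyCodonChange <- function(ref, alt) {
  if (nchar(ref) != 3L || nchar(alt) != 3L)
    stop("codons must be 3 nt", call. = FALSE)
  if (ref == alt) return("none")
  if (.geneticCode()[[ref]] == .geneticCode()[[alt]]) "silent" else "replacement"
}

# Compare two equal-length nt strings column-wise; unequal lengths are
# aligned and gap columns excluded (returned as nIndel).
.ntCompare <- function(a, b) {
  if (nchar(a) == nchar(b))
    return(list(diff = .posDiff(a, b), nTotal = nchar(a), nIndel = 0L))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = .nucMat(),
    gapOpening = 4, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- pa == "-" | sa == "-"
  aPos <- cumsum(pa != "-")
  list(diff = aPos[!gap & pa != sa], nTotal = sum(!gap),
       nIndel = sum(gap))
}

#' Region-wise silent and replacement changes between two transcripts
#'
#' Compares the conceptual transcripts of two annotated clones region by
#' region (utr5, signal, Ig-V, TM, tail, final exon). Coding regions are
#' compared codon against codon; a changed codon is classified silent when
#' both codons encode the same amino acid and replacement otherwise, from
#' whole-codon comparison even when several nucleotides changed. Repeat
#' units of the tail are aligned as whole units, so different repeat-exon
#' counts appear as excluded indel blocks rather than spurious mismatches.
#'
#' @param ref,alt [TranscriptAnnotation] objects on the same architecture.
#' @param accounting `"per_position"` (each changed nucleotide contributes
#'   one silent-or-replacement count; the convention behind published
#'   per-position tallies) or `"per_codon"` (each changed codon contributes
#'   one count).
#' @return `data.frame` with one row per region: `region`, `nNt`,
#'   `nVariableNt`, `nAa`, `nSilent`, `nReplacement`, `nIndelNt`; the
#'   per-position detail is in `attr(, "positions")`.
#' @examples
#' # identical transcripts compare to all-zero variation
#' gm <- canonicalGeneModel(nRepeats = 4)
#' a <- annotateClone(spliceModel(gm), gm)
#' compareRegions(a, a)
#' @export
compareRegions <- function(ref, alt,
                           accounting = c("per_position", "per_codon")) {
  accounting <- match.arg(accounting)
  refR <- .codonsByRegion(ref); altR <- .codonsByRegion(alt)
  rows <- list(); details <- list()
  addDetail <- function(region, codonIndex, position, refState, altState, cls)
    details[[length(details) + 1L]] <<- data.frame(
      region = region, codonIndex = codonIndex, position = position,
      refState = refState, altState = altState, class = cls,
      stringsAsFactors = FALSE)
  # utr5: nucleotide comparison
  u <- .ntCompare(.utr5Of(ref), .utr5Of(alt))
  uref <- strsplit(.utr5Of(ref), "")[[1]]
  ualt <- strsplit(.utr5Of(alt), "")[[1]]
  for (p in u$diff)
    addDetail("utr5", NA_integer_, p, uref[p],
              if (nchar(.utr5Of(alt)) >= p) ualt[p] else "-", NA_character_)
  rows[["utr5"]] <- data.frame(
    region = "utr5", nNt = u$nTotal, nVariableNt = length(u$diff),
    nAa = 0L, nSilent = 0L, nReplacement = 0L, nIndelNt = u$nIndel,
    stringsAsFactors = FALSE)
  for (reg in .codingRegions) {
    rc <- refR[[reg]]; ac <- altR[[reg]]
    nIndel <- 0L
    if (reg == "tail") {
      # align repeat units as blocks
      ru <- split(rc, rc$unitIndex); au <- split(ac, ac$unitIndex)
      path <- .blockNW(ru, au,
                       function(x, y) {
                         n <- min(nrow(x), nrow(y))
                         sum(x$codon[seq_len(n)] == y$codon[seq_len(n)]) -
                           3L * abs(nrow(x) - nrow(y))
                       }, gap = -4)
      pairs <- list()
      for (r in seq_len(nrow(path))) {
        i <- path[r, 1L]; j <- path[r, 2L]
        if (is.na(i) || is.na(j)) {
          nIndel <- nIndel + 3L * if (is.na(i)) nrow(au[[j]]) else nrow(ru[[i]])
        } else if (nrow(ru[[i]]) != nrow(au[[j]])) {
          nIndel <- nIndel + 3L * (nrow(ru[[i]]) + nrow(au[[j]]))
        } else {
          pairs[[length(pairs) + 1L]] <- list(ru[[i]], au[[j]])
        }
      }
      rcc <- do.call(rbind, lapply(pairs, `[[`, 1L))
      acc <- do.call(rbind, lapply(pairs, `[[`, 2L))
    } else {
      n <- min(nrow(rc), nrow(ac))
      if (reg %in% c("signal", "igv", "tm") && nrow(rc) != nrow(ac))
        stop("frame inconsistency in region ", reg, call. = FALSE)
      nIndel <- nIndel + 3L * (nrow(rc) - n) + 3L * (nrow(ac) - n)
      rcc <- rc[seq_len(n), , drop = FALSE]
      acc <- ac[seq_len(n), , drop = FALSE]
    }
    nSil <- 0L; nRep <- 0L; nVar <- 0L
    if (!is.null(rcc) && nrow(rcc)) {
      for (ci in seq_len(nrow(rcc))) {
        d <- .posDiff(rcc$codon[ci], acc$codon[ci])
        if (!length(d)) next
        cls <- classifyCodonChange(rcc$codon[ci], acc$codon[ci])
        inc <- if (accounting == "per_position") length(d) else 1L
        if (cls == "silent") nSil <- nSil + inc else nRep <- nRep + inc
        nVar <- nVar + length(d)
        for (p in d)
          addDetail(reg, ci, 3L * (ci - 1L) + p,
                    substr(rcc$codon[ci], p, p), substr(acc$codon[ci], p, p),
                    cls)
      }
    }
    nCod <- if (is.null(rcc)) 0L else nrow(rcc)
    nNt <- 3L * nCod
    # the untranslated remainder of the final exon is compared as nt
    if (reg == "final_exon") {
      cdsR <- as.character(ref@conceptualCds)
      cdsA <- as.character(alt@conceptualCds)
      nTransR <- sum(ref@codonsConceptual$translated)
      nTransA <- sum(alt@codonsConceptual$translated)
      utrR <- substr(cdsR, 3L * nTransR + 1L, nchar(cdsR))
      utrA <- substr(cdsA, 3L * nTransA + 1L, nchar(cdsA))
      u3 <- .ntCompare(utrR, utrA)
      u3ref <- strsplit(utrR, "")[[1]]
      for (p in u3$diff)
        addDetail("final_exon", NA_integer_, nNt + p, u3ref[p], "", NA_character_)
      nVar <- nVar + length(u3$diff)
      nNt <- nNt + u3$nTotal
      nIndel <- nIndel + u3$nIndel
    }
    rows[[reg]] <- data.frame(
      region = reg, nNt = nNt, nVariableNt = nVar, nAa = nCod,
      nSilent = nSil, nReplacement = nRep, nIndelNt = nIndel,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "positions") <- if (length(details)) do.call(rbind, details) else
    data.frame(region = character(), codonIndex = integer(),
               position = integer(), refState = character(),
               altState = character(), class = character(),
               stringsAsFactors = FALSE)
  out
}

#' Replacement:silent summary against the neutral 2:1 expectation
#'
#' Pools silent/replacement counts per region over one or more pairwise
#' comparisons and reports the replacement:silent ratio. Under neutral
#' evolution random changes are expected to yield roughly two replacements
#' per silent change, so a ratio above 2 is flagged as consistent with
#' selection; at or below 2, not consistent with strong selection. No
#' p-value is computed: the 2:1 heuristic is the whole test.
#'
#' @param comparisons A comparison `data.frame` from [compareRegions()] or
#'   a list of them.
#' @return `data.frame`: `region`, `nSilent`, `nReplacement`, `ratio`,
#'   `flag` (`"consistent with selection"`,
#'   `"not consistent with strong selection"` or
#'   `"undefined (no silent changes)"`).
#' @examples
#' x <- data.frame(region = "igv", nSilent = 7, nReplacement = 12)
#' selectionSummary(x)  # 12/7 < 2: not consistent with strong selection
#' @export
selectionSummary <- function(comparisons) {
  if (is.data.frame(comparisons)) comparisons <- list(comparisons)
  all <- do.call(rbind, lapply(comparisons, function(x)
    x[, c("region", "nSilent", "nReplacement")]))
  agg <- stats::aggregate(cbind(nSilent, nReplacement) ~ region, all, sum)
  agg$ratio <- ifelse(agg$nSilent > 0, agg$nReplacement / agg$nSilent, NA_real_)
  agg$flag <- ifelse(agg$nSilent == 0,
                     "undefined (no silent changes)",
                     ifelse(agg$ratio > 2, "consistent with selection",
                            "not consistent with strong selection"))
  agg
}

#' Census of variable positions over aligned sequences
#'
#' Counts alignment columns holding more than one state among the input
#' sequences. Columns containing a gap are counted separately as indel
#' columns and excluded from the total; masked columns (e.g. primer-binding
#' sites) are excluded from both.
#'
#' @param seqs Character vector (or XStringSet) of aligned, equal-length
#'   sequences.
#' @param mask Optional integer vector of columns to exclude.
#' @return List: `nVariable`, `nTotal`, `nIndelColumns`,
#'   `variablePositions` (column indices).
#' @examples
#' variablePositionCensus(c("ACGT", "ACTT", "ACGT"))
#' @export
variablePositionCensus <- function(seqs, mask = NULL) {
  seqs <- as.character(seqs)
  if (length(seqs) < 1L || any(nchar(seqs) == 0L))
    stop("census requires non-empty sequences", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must be aligned to equal length", call. = FALSE)
  m <- do.call(rbind, strsplit(seqs, ""))
  L <- ncol(m)
  cols <- setdiff(seq_len(L), mask)
  isGap <- apply(m[, cols, drop = FALSE] == "-", 2L, any)
  nStates <- apply(m[, cols, drop = FALSE], 2L, function(x) length(unique(x)))
  variable <- cols[!isGap & nStates > 1L]
  list(nVariable = length(variable),
       nTotal = sum(!isGap),
       nIndelColumns = sum(isGap),
       variablePositions = variable)
}
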