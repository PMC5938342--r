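# The heptad register implied by a codon's position within the 21-nt repeat
# unit. The repeat unit's first codon is split (phase 1), and the mostly
# hydrophobic residues sit at codons 4 and 7, so the register frame is
# offset: codon 4 is 'a' and codon 7 is 'd'.
.registerMap <- c("e", "f", "g", "a", "b", "c", "d")

#' Register letter for a repeat-unit codon position
#'
#' @param codonPos Integer vector of codon positions within the 21-nt
#'   repeat unit (1--7; larger values wrap into the next heptad).
#' @return Character vector of register letters `a`--`g`.
#' @examples
#' registerOfCodon(c(1, 4, 7))  # e a d
#' @export
registerOfCodon <- function(codonPos) {
  .registerMap[(as.integer(codonPos) - 1L) %% 7L + 1L]
}

.chemTable <- c(
  D = "acidic", E = "acidic",
  K = "basic", R = "basic", H = "basic",
  C = "cysteine",
  S = "polar", T = "polar", N = "polar", Q = "polar", Y = "polar",
  G = "glycine_proline", P = "glycine_proline",
  A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
  I = "hydrophobic", M = "hydrophobic", F = "hydrophobic",
  W = "hydrophobic")

#' Chemical class of an amino acid
#'
#' The fixed partition used to decorate helical wheels: acidic (D, E),
#' basic (K, R, H), cysteine on its own, polar (S, T, N, Q, Y),
#' glycine/proline as a helix-breaking sub-class, and the remainder
#' hydrophobic. Histidine-as-basic and tyrosine-as-polar are conventions
#' this partition fixes explicitly.
#'
#' @param aa Character vector of single-letter amino-acid codes.
#' @return Character vector of classes.
#' @examples
#' classifyResidue(c("E", "C", "L"))
#' @export
classifyResidue <- function(aa) {
  aa <- toupper(aa)
  bad <- !aa %in% names(.chemTable)
  if (any(bad))
    stop("nonstandard amino acid(s): ", paste(unique(aa[bad]), collapse = ", "),
         call. = FALSE)
  unname(.chemTable[aa])
}

#' Build a register table from a tail protein and its repeat-unit structure
#'
#' Assigns each cytoplasmic-tail residue its heptad register via the
#' split-codon rule: register depends only on the residue's codon position
#' within its 21-nt repeat unit, never on the absolute residue index, so
#' the assignment is invariant to where translation started.
#'
#' @param tailProtein Tail residues (character string or vector).
#' @param unitLengths Integer vector: residues contributed by each repeat
#'   unit, in order (default: complete heptads of 7). Must sum to the tail
#'   length; a shorter final unit is allowed.
#' @param sourceExon Optional integer vector (per unit) of source exons.
#' @return `data.frame` with one row per residue: `heptadIndex`,
#'   `codonPos`, `register`, `residue`, `chemClass`, `variable`,
#'   `sourceExon`.
#' @export
assignRegister <- function(tailProtein,
                           unitLengths = NULL,
                           sourceExon = NULL) {
  res <- if (length(tailProtein) == 1L) strsplit(tailProtein, "")[[1]]
         else as.character(tailProtein)
  n <- length(res)
  if (is.null(unitLengths)) {
    unitLengths <- rep(7L, n %/% 7L)
    if (n %% 7L) unitLengths <- c(unitLengths, n %% 7L)
  }
  if (sum(unitLengths) != n)
    stop("unitLengths must sum to the tail length (residue without ",
         "codon-position provenance)", call. = FALSE)
  unit <- rep(seq_along(unitLengths), unitLengths)
  codonPos <- unlist(lapply(unitLengths, seq_len))
  data.frame(
    heptadIndex = unit,
    codonPos = codonPos,
    register = registerOfCodon(codonPos),
    residue = res,
    chemClass = classifyResidue(res),
    variable = FALSE,
    sourceExon = if (is.null(sourceExon)) NA_integer_ else
      rep(sourceExon, unitLengths),
    stringsAsFactors = FALSE)
}

#' Register table of an annotated clone's cytoplasmic tail
#'
#' @param annotation A [TranscriptAnnotation].
#' @param which Use the conceptual (default) or actual transcript.
#' @return A register `data.frame` as from [assignRegister()].
#' @export
tailRegisterTable <- function(annotation,
                              which = c("conceptual", "actual")) {
  which <- match.arg(which)
  cod <- if (which == "conceptual") annotation@codonsConceptual
         else annotation@codonsActual
  cod <- cod[cod$translated & cod$region %in% c("tail", "final_exon") &
               !is.na(cod$codonPos), , drop = FALSE]
  if (!nrow(cod))
    return(data.frame(heptadIndex = integer(), codonPos = integer(),
                      register = character(), residue = character(),
                      chemClass = character(), variable = logical(),
                      sourceExon = integer()))
  data.frame(
    heptadIndex = cod$unitIndex,
    codonPos = cod$codonPos,
    register = registerOfCodon(cod$codonPos),
    residue = cod$aa,
    chemClass = classifyResidue(cod$aa),
    variable = FALSE,
    sourceExon = cod$exonIndex,
    stringsAsFactors = FALSE)
}

#' Fraction of hydrophobic residues at each register position
#'
#' Quantifies the hydrophobic interface of the coiled coil: in BG tails the
#' `a` and `d` registers (repeat-unit codons 4 and 7) should far exceed the
#' other five positions.
#'
#' @param table A register `data.frame`.
#' @return Named numeric vector over registers `a`--`g` (NA where a
#'   register has no residues).
#' @export
interfaceHydrophobicity <- function(table) {
  out <- stats::setNames(rep(NA_real_, 7L), c("a", "b", "c", "d", "e", "f", "g"))
  if (!nrow(table)) return(out)
  fr <- tapply(table$chemClass == "hydrophobic", table$register, mean)
  out[names(fr)] <- fr
  out
}

# Align two register tables at whole-heptad granularity; returns a
# two-column index matrix over heptad blocks (NA = gap). Gaps are only
# allowed in complete repeat units, mirroring the exon-unit insertions
# seen in BG tails.
.alignHeptads <- function(ta, tb) {
  blocksOf <- function(t) {
    hs <- sort(unique(t$heptadIndex))
    lapply(hs, function(h) t$residue[t$heptadIndex == h][order(t$codonPos[t$heptadIndex == h])])
  }
  ba <- blocksOf(ta); bb <- blocksOf(tb)
  score <- function(x, y) {
    n <- min(length(x), length(y))
    sum(x[seq_len(n)] == y[seq_len(n)]) - abs(length(x) - length(y))
  }
  .blockNW(ba, bb, score, gap = -4)
}

#' Mark and summarise variable positions across aligned tails
#'
#' Aligns the cytoplasmic tails of two or more sequences at whole-heptad
#' granularity (insertions such as a tandem block of extra repeat exons
#' align as whole units), marks positions where the aligned residues
#' differ, and tallies them per register letter. Inserted heptads are
#' reported separately and excluded from the shared-position counts. The
#' summary is symmetric in input order up to relabelling of the reference.
#'
#' @param tables Named list of at least two register `data.frame`s (the
#'   first is the coordinate reference).
#' @return List with `positions` (`data.frame`: `heptadIndex`, `codonPos`,
#'   `register`, `states`, `nStates`), `countsByRegister` (named integer),
#'   `insertions` (`data.frame`: `sequence`, `nInsertedHeptads`) and
#'   `diAllelic` (logical: every variable position has exactly two
#'   states).
#' @export
decorateVariation <- function(tables) {
  if (length(tables) < 2L) stop("need at least two tails", call. = FALSE)
  if (is.null(names(tables)))
    names(tables) <- paste0("seq", seq_along(tables))
  ref <- tables[[1L]]
  refH <- sort(unique(ref$heptadIndex))
  getRes <- function(t, h, cp) {
    v <- t$residue[t$heptadIndex == h & t$codonPos == cp]
    if (length(v)) v[1L] else NA_character_
  }
  # map each non-reference table's heptads onto the reference's
  maps <- list()
  insertions <- data.frame(sequence = character(), nInsertedHeptads = integer(),
                           stringsAsFactors = FALSE)
  for (k in seq_along(tables)[-1L]) {
    path <- .alignHeptads(ref, tables[[k]])
    hk <- sort(unique(tables[[k]]$heptadIndex))
    map <- rep(NA_integer_, length(refH))
    ins <- 0L
    for (r in seq_len(nrow(path))) {
      i <- path[r, 1L]; j <- path[r, 2L]
      if (!is.na(i) && !is.na(j)) map[i] <- hk[j]
      if (is.na(i) && !is.na(j)) ins <- ins + 1L
    }
    maps[[names(tables)[k]]] <- map
    insertions <- rbind(insertions, data.frame(
      sequence = names(tables)[k], nInsertedHeptads = ins,
      stringsAsFactors = FALSE))
  }
  rows <- list()
  for (hi in seq_along(refH)) {
    h <- refH[hi]
    cps <- sort(ref$codonPos[ref$heptadIndex == h])
    for (cp in cps) {
      states <- getRes(ref, h, cp)
      for (k in seq_along(tables)[-1L]) {
        hk <- maps[[names(tables)[k]]][hi]
        if (is.na(hk)) next  # deletion in this sequence: not a shared position
        states <- c(states, getRes(tables[[k]], hk, cp))
      }
      states <- states[!is.na(states)]
      us <- unique(states)
      if (length(us) > 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          heptadIndex = h, codonPos = cp,
          register = registerOfCodon(cp),
          states = paste(sort(us), collapse = "/"),
          nStates = length(us), stringsAsFactors = FALSE)
      }
    }
  }
  positions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(heptadIndex = integer(), codonPos = integer(),
               register = character(), states = character(),
               nStates = integer(), stringsAsFactors = FALSE)
  counts <- stats::setNames(integer(7L), c("a", "b", "c", "d", "e", "f", "g"))
  if (nrow(positions)) {
    tb <- table(positions$register)
    counts[names(tb)] <- as.integer(tb)
  }
  list(positions = positions, countsByRegister = counts,
       insertions = insertions,
       diAllelic = !nrow(positions) || all(positions$nStates == 2L))
}

#' Detect charge/polarity patches along the coiled coil
#'
#' Slides a window of `window` heptads along the tail and, looking only at
#' the five non-interface registers (b, c, e, f, g; a and d form the
#' hydrophobic stripe between the chains), reports maximal merged windows
#' in which one chemical class reaches at least `threshold` of the
#' positions. With the defaults this picks up the acidic, basic and polar
#' patches of BG tails, including the acidic patch at the C-terminus.
#'
#' @param table A register `data.frame`.
#' @param window Window length in heptads (>= 2, default 4).
#' @param threshold Minimum class fraction within a window (default 0.6).
#' @param classes Chemical classes to scan for.
#' @return `data.frame` of patch calls: `chemClass`, `startHeptad`,
#'   `endHeptad`, `enrichment` (class fraction over the merged span).
#' @export
findPatches <- function(table, window = 4L, threshold = 0.6,
                        classes = c("acidic", "basic", "polar")) {
  if (window < 2L) stop("window must be at least 2 heptads", call. = FALSE)
  none <- data.frame(chemClass = character(), startHeptad = integer(),
                     endHeptad = integer(), enrichment = numeric(),
                     stringsAsFactors = FALSE)
  ni <- table[table$register %in% c("b", "c", "e", "f", "g"), , drop = FALSE]
  if (!nrow(ni)) return(none)
  hs <- sort(unique(ni$heptadIndex))
  if (length(hs) < window) return(none)
  starts <- hs[seq_len(length(hs) - window + 1L)]
  calls <- list()
  for (cl in classes) {
    qual <- logical(length(starts))
    for (si in seq_along(starts)) {
      span <- hs[si:(si + window - 1L)]
      inw <- ni[ni$heptadIndex %in% span, , drop = FALSE]
      qual[si] <- nrow(inw) > 0 && mean(inw$chemClass == cl) >= threshold
    }
    if (!any(qual)) next
    # merge overlapping qualifying windows into maximal spans
    qi <- which(qual)
    brk <- c(0L, which(diff(qi) >= window), length(qi))
    for (b in seq_len(length(brk) - 1L)) {
      grp <- qi[(brk[b] + 1L):brk[b + 1L]]
      s <- starts[grp[1L]]
      e <- hs[grp[length(grp)] + window - 1L]
      inw <- ni[ni$heptadIndex >= s & ni$heptadIndex <= e, , drop = FALSE]
      nCl <- sum(inw$chemClass == cl)
      if (nCl == 0L) next
      calls[[length(calls) + 1L]] <- data.frame(
        chemClass = cl, startHeptad = s, endHeptad = e,
        enrichment = nCl / nrow(inw), stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) return(none)
  out <- do.call(rbind, calls)
  out[order(out$startHeptad, out$chemClass), , drop = FALSE]
}

#' Text helical-wheel rendering of a register table
#'
#' One row per repeat unit, seven columns for codon positions 1--7 with
#' their register letters in the header; a stable, bit-exact layout suited
#' to diffing.
#'
#' @param table A register `data.frame`.
#' @return Character vector of lines, invisibly; also printed.
#' @export
wheelText <- function(table) {
  header <- paste0("unit |", paste(sprintf(" %d(%s)", 1:7, .registerMap),
                                   collapse = ""))
  lines <- header
  for (h in sort(unique(table$heptadIndex))) {
    row <- table[table$heptadIndex == h, , drop = FALSE]
    cells <- vapply(1:7, function(cp) {
      r <- row$residue[row$codonPos == cp]
      if (length(r)) sprintf("  %s  ", r[1L]) else "  .  "
    }, character(1L))
    lines <- c(lines, sprintf("%4d |%s", h, paste(substr(cells, 1, 5), collapse = "")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
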