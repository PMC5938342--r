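# Shared fixtures and independent oracles, all built in code.

# A small gene family with configurable divergence; zero artefacts unless
# asked for.
quickFamily <- function(seed, repeats = c(6L, 5L), stopHeptads = c(1L, 0L),
                        rates = NULL, depth = 1L, retention = 0,
                        chimeras = 0L, errors = 0L, ...) {
  if (is.null(rates))
    rates <- c(utr5 = 0.02, signal = 0.02, igv = 0.015, tm = 0.02,
               tail = 0.01, final_exon = 0.01)
  cfg <- simulationConfig(seed = seed, repeatExonCounts = repeats,
                          stopHeptads = stopHeptads, rates = rates,
                          intronRetentionProb = retention,
                          chimeraCount = chimeras,
                          singletonErrorCount = errors,
                          cloneDepth = depth, ...)
  fam <- simulateGeneFamily(cfg)
  lib <- simulateCloneLibrary(fam$genes, cfg)
  list(cfg = cfg, genes = fam$genes, ancestor = fam$ancestor,
       famTruth = fam$truth, lib = lib$library, truth = lib$truth)
}

zeroRates <- c(utr5 = 0, signal = 0, igv = 0, tm = 0, tail = 0,
               final_exon = 0)

# --- oracles ---------------------------------------------------------------

# Exhaustive window-scan for IUPAC primer sites (plus and minus strand).
oraclePrimerScan <- function(seq, primer) {
  map <- Biostrings::IUPAC_CODE_MAP
  hits1 <- function(pat, strand) {
    pc <- strsplit(pat, "")[[1]]
    w <- length(pc)
    sc <- strsplit(seq, "")[[1]]
    out <- NULL
    for (s in seq_len(nchar(seq) - w + 1L)) {
      win <- sc[s:(s + w - 1L)]
      mm <- sum(!mapply(function(p, x) grepl(x, map[[p]], fixed = TRUE),
                        pc, win))
      if (mm == 0L)
        out <- rbind(out, data.frame(start = s, end = s + w - 1L,
                                     strand = strand, mismatches = 0L))
    }
    out
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(primer)))
  out <- rbind(hits1(primer, "+"), hits1(rc, "-"))
  if (is.null(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force codon walk: translate a spliced transcript from its ATG,
# halting at the first stop. Independent of the annotation machinery.
oracleTranslate <- function(transcript, utr5Len) {
  cds <- substr(transcript, utr5Len + 1L, nchar(transcript))
  n <- nchar(cds) %/% 3L
  aas <- character(0)
  for (i in seq_len(n)) {
    codon <- substr(cds, 3L * i - 2L, 3L * i)
    aa <- as.character(Biostrings::GENETIC_CODE[[codon]])
    if (aa == "*") return(paste(aas, collapse = ""))
    aas <- c(aas, aa)
  }
  paste(aas, collapse = "")
}

# Brute-force patch enumeration: all windows of exactly `window` heptads
# over non-interface positions; overlapping qualifying windows of one class
# merged into maximal spans; spans without any class member dropped.
oraclePatches <- function(table, window, threshold,
                          classes = c("acidic", "basic", "polar")) {
  emptyCalls <- data.frame(chemClass = character(), startHeptad = integer(),
                           endHeptad = integer(), enrichment = numeric(),
                           stringsAsFactors = FALSE)
  ni <- table[table$register %in% c("b", "c", "e", "f", "g"), , drop = FALSE]
  hs <- sort(unique(ni$heptadIndex))
  out <- NULL
  if (length(hs) < window) return(emptyCalls)
  for (cl in classes) {
    spans <- NULL
    for (si in seq_len(length(hs) - window + 1L)) {
      span <- hs[si:(si + window - 1L)]
      inw <- ni[ni$heptadIndex %in% span, , drop = FALSE]
      if (nrow(inw) && mean(inw$chemClass == cl) >= threshold)
        spans <- rbind(spans, c(si, si + window - 1L))
    }
    if (is.null(spans)) next
    # merge overlapping index spans
    merged <- list(spans[1L, ])
    if (nrow(spans) > 1L) for (r in 2L:nrow(spans)) {
      last <- merged[[length(merged)]]
      if (spans[r, 1L] <= last[2L])
        merged[[length(merged)]] <- c(last[1L], max(last[2L], spans[r, 2L]))
      else merged[[length(merged) + 1L]] <- spans[r, ]
    }
    for (m in merged) {
      s <- hs[m[1L]]; e <- hs[m[2L]]
      inw <- ni[ni$heptadIndex >= s & ni$heptadIndex <= e, , drop = FALSE]
      nCl <- sum(inw$chemClass == cl)
      if (nCl == 0L) next
      out <- rbind(out, data.frame(chemClass = cl, startHeptad = s,
                                   endHeptad = e,
                                   enrichment = nCl / nrow(inw),
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) return(emptyCalls)
  out <- out[order(out$startHeptad, out$chemClass), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random register table with uniform residues (seeded by caller).
randomRegisterTable <- function(nHeptads) {
  aa <- sample(names(bgalleles:::.chemTable), nHeptads * 7L, replace = TRUE)
  assignRegister(paste(aa, collapse = ""))
}
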