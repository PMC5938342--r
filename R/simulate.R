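#' Configuration for the synthetic BG data generator
#'
#' Bundles and validates every knob of the generator. The defaults emulate
#' the architecture and divergence observed for expressed BG genes: four
#' genes with 33, 28, 31 and 27 repeat exons (BG8-, BG9-, BG12- and
#' BG13-like), a stop after one complete repeat in the final exon for the
#' 28-exon gene (29 apparent heptads) and a stop at the start of the final
#' exon otherwise, per-nucleotide substitution rates of 1--2% per region
#' (the alleles under study differ by well under 7% in any region), and an
#' intron-retention probability of 0.2 per intron per transcript.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param repeatExonCounts Integer vector, repeat exons per gene.
#' @param stopHeptads Integer vector (recycled), complete heptads encoded by
#'   the final exon of each gene before its stop codon (0 = the stop codon
#'   immediately follows the completed boundary-split codon).
#' @param rates Named per-nucleotide substitution probabilities for regions
#'   `utr5`, `signal`, `igv`, `tm`, `tail`, `final_exon` (and optionally
#'   `intron`).
#' @param intronRetentionProb Probability that a given intron is retained in
#'   a given transcript.
#' @param chimeraCount Number of single-crossover chimeric clones to plant.
#' @param singletonErrorCount Number of clones carrying a single planted
#'   mis-incorporation substitution, each present once in one PCR batch.
#' @param cloneDepth Clones per gene (recycled over genes).
#' @param nBatches Number of PCR batches clones are assigned to.
#' @param line Chicken line identifier stamped on all clones.
#' @param intronLengthRange Intron lengths are drawn uniformly from this
#'   range (nt).
#' @param oddRepeatLens Optional list, one element per gene, of named
#'   integer vectors giving 18/24-nt exceptions for specific repeat exons,
#'   e.g. `list(NULL, c("5" = 18))`.
#' @param ancestorRepeatCount Repeat exons in the ancestral gene (default:
#'   the maximum of `repeatExonCounts`). A gene requesting more repeats
#'   than the ancestor acquires them by tandem duplication of one of its
#'   cassettes, emulating the apparent exon insertions seen in real BG
#'   genes.
#' @return A validated list of class `"SimulationConfig"`.
#' @seealso [simulateGeneFamily()], [simulateCloneLibrary()]
#' @export
simulationConfig <- function(seed = 1L,
                             repeatExonCounts = c(33L, 28L, 31L, 27L),
                             stopHeptads = c(0L, 1L, 0L, 0L),
                             rates = c(utr5 = 0.02, signal = 0.02,
                                       igv = 0.015, tm = 0.02,
                                       tail = 0.01, final_exon = 0.01),
                             intronRetentionProb = 0.2,
                             chimeraCount = 0L,
                             singletonErrorCount = 0L,
                             cloneDepth = 10L,
                             nBatches = 2L,
                             line = "S",
                             intronLengthRange = c(80L, 300L),
                             oddRepeatLens = NULL,
                             ancestorRepeatCount = NULL) {
  nGenes <- length(repeatExonCounts)
  if (nGenes < 1L) stop("config error: need at least one gene", call. = FALSE)
  if (any(repeatExonCounts < 0L))
    stop("config error: repeat exon counts must be >= 0", call. = FALSE)
  stopHeptads <- rep_len(as.integer(stopHeptads), nGenes)
  if (any(stopHeptads < 0L))
    stop("config error: stopHeptads must be >= 0", call. = FALSE)
  if (any(rates < 0 | rates > 1))
    stop("config error: rates must be probabilities", call. = FALSE)
  if (intronRetentionProb < 0 || intronRetentionProb > 1)
    stop("config error: intronRetentionProb must be in [0,1]", call. = FALSE)
  if (chimeraCount < 0L || singletonErrorCount < 0L)
    stop("config error: counts must be >= 0", call. = FALSE)
  cloneDepth <- rep_len(as.integer(cloneDepth), nGenes)
  structure(list(
    seed = as.integer(seed),
    repeatExonCounts = as.integer(repeatExonCounts),
    stopHeptads = stopHeptads,
    rates = rates,
    intronRetentionProb = intronRetentionProb,
    chimeraCount = as.integer(chimeraCount),
    singletonErrorCount = as.integer(singletonErrorCount),
    cloneDepth = cloneDepth,
    nBatches = as.integer(nBatches),
    line = as.character(line),
    intronLengthRange = as.integer(intronLengthRange),
    oddRepeatLens = oddRepeatLens,
    ancestorRepeatCount = if (is.null(ancestorRepeatCount)) NULL else
      as.integer(ancestorRepeatCount)
  ), class = "SimulationConfig")
}

# ---- ancestor construction ------------------------------------------------

# Resolve an IUPAC primer to a concrete sequence (first base of each
# ambiguity set, so Y -> C and N -> A).
.resolvePrimer <- function(primer) {
  chars <- strsplit(toupper(primer), "")[[1]]
  paste(vapply(chars, function(ch)
    substr(Biostrings::IUPAC_CODE_MAP[[ch]], 1L, 1L), character(1L)),
    collapse = "")
}

# Every phase-1 exon junction in generated genes uses invariant nucleotides:
# the donor exon ends in "G" and the acceptor exon begins with "AG", so the
# boundary-split codon is always GAG (Glu, an e-position residue). This
# makes whole repeat-exon cassettes freely insertable/deletable without
# creating frameshifts or junction stop codons.
.JUNC_TAIL <- "G"
.JUNC_HEAD <- "AG"

# One repeat exon of len nt (18/21/24): AG completing the split codon,
# len/3 - 1 full sense codons, and a trailing G starting the next split
# codon.
.makeRepeatExon <- function(len) {
  stopifnot(len %% 3L == 0L)
  nFull <- len %/% 3L - 1L
  paste0(.JUNC_HEAD,
         paste(.randomSenseCodons(nFull), collapse = ""),
         .JUNC_TAIL)
}

# Final-exon coding: AG (completing the split codon) + complete heptads + TAA.
.makeFinalCoding <- function(k) {
  if (k > 0L)
    paste0(.JUNC_HEAD, paste(.randomSenseCodons(7L * k - 1L), collapse = ""), "TAA")
  else
    paste0(.JUNC_HEAD, "TAA")
}

.makeIntron <- function(range) {
  len <- sample(range[1L]:range[2L], 1L)
  paste0("GT", .randomDna(len - 4L), "AG")
}

# Build a BG-like gene from parts; consumes the current RNG stream.
# Returns list(exonSeqs, intronSeqs, kinds, phases, utr5Length, finalCoding).
.buildGeneParts <- function(nRepeats, stopHeptads, intronLengthRange,
                            repeatLens = NULL, finalExonWidth = 411L) {
  primers <- bgPrimers()
  fwdSite <- .resolvePrimer(primers[["UC206"]])
  revSite <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(.resolvePrimer(primers[["UC650"]]))))
  utr5 <- paste0(fwdSite, .randomDna(137L))
  e1 <- paste0(utr5, "ATG",
               paste(.randomSenseCodons(31L), collapse = ""), .JUNC_TAIL)
  e2 <- paste0(.JUNC_HEAD, paste(.randomSenseCodons(114L), collapse = ""))
  tm <- paste0(paste(.randomSenseCodons(33L), collapse = ""), .JUNC_TAIL)
  if (is.null(repeatLens)) repeatLens <- rep(21L, nRepeats)
  reps <- vapply(repeatLens, .makeRepeatExon, character(1L))
  finalCoding <- .makeFinalCoding(stopHeptads)
  utr3len <- finalExonWidth - nchar(finalCoding) - nchar(revSite)
  if (utr3len < 0L)
    stop("config error: final exon cannot hold ", stopHeptads,
         " heptads within ", finalExonWidth, " nt", call. = FALSE)
  fin <- paste0(finalCoding, .randomDna(utr3len), revSite)
  exonSeqs <- c(e1, e2, tm, reps, fin)
  nIntrons <- length(exonSeqs) - 1L
  intronSeqs <- vapply(seq_len(nIntrons), function(i)
    .makeIntron(intronLengthRange), character(1L))
  list(exonSeqs = exonSeqs, intronSeqs = intronSeqs,
       kinds = c("utr5_signal", "igv", "tm",
                 rep("repeat", length(reps)), "final"),
       phases = c(0L, 1L, 0L, rep(1L, length(reps)), 1L),
       utr5Length = nchar(utr5), finalCoding = finalCoding)
}

.assembleModel <- function(name, parts) {
  n <- length(parts$exonSeqs)
  pieces <- character(2L * n - 1L)
  pieces[seq(1L, 2L * n - 1L, by = 2L)] <- parts$exonSeqs
  if (n > 1L) pieces[seq(2L, 2L * n - 2L, by = 2L)] <- parts$intronSeqs
  genomic <- paste(pieces, collapse = "")
  w <- nchar(parts$exonSeqs)
  iw <- c(nchar(parts$intronSeqs), 0L)
  starts <- integer(n); pos <- 1L
  for (i in seq_len(n)) {
    starts[i] <- pos
    pos <- pos + w[i] + iw[i]
  }
  GeneModel(name, genomic,
            data.frame(start = starts, end = starts + w - 1L,
                       kind = parts$kinds, phase = parts$phases),
            parts$utr5Length)
}

#' The bundled canonical BG gene model
#'
#' A synthetic gene with the canonical architecture: one 5'UTR/signal exon
#' (26-nt forward-primer site + 137-nt 5'UTR + 99-nt signal), one Ig-V exon
#' (342 nt of Ig-V preceded by the 2 nt completing the split signal codon),
#' one TM exon, `nRepeats` repeat exons of 21 nt, and a 411-nt final exon
#' ending in the reverse-primer site. The sequence itself is synthetic
#' (deterministically generated); the published BG sequences live in GenBank
#' and are not bundled.
#'
#' @param nRepeats Number of 21-nt repeat exons (default 33, BG8-like).
#' @param stopHeptads Complete heptads encoded by the final exon before its
#'   stop (default 0: stop at the start of the final exon).
#' @param seed Seed for the deterministic construction.
#' @return A [GeneModel].
#' @export
canonicalGeneModel <- function(nRepeats = 33L, stopHeptads = 0L,
                               seed = 20180521L) {
  .withSeed(seed, .assembleModel(
    "BG_canonical",
    .buildGeneParts(nRepeats, stopHeptads, c(80L, 300L))))
}

# ---- gene family ----------------------------------------------------------

# Positions (on a model's genomic sequence) that substitutions must never
# touch: primer sites, start and stop codons, splice dinucleotides and the
# invariant phase-1 junction nucleotides.
.immutableMask <- function(model, finalCodingLen) {
  ex <- model@exons
  kind <- .exonKinds(model)
  phase <- .exonPhases(model)
  st <- IRanges::start(ex); en <- IRanges::end(ex)
  mask <- integer(0)
  mask <- c(mask, st[1L]:(st[1L] + 25L))                      # fwd primer site
  fin <- length(ex)
  mask <- c(mask, (en[fin] - 23L):en[fin])                    # rev primer site
  atg <- st[1L] + model@utr5Length
  mask <- c(mask, atg:(atg + 2L))                             # start codon
  stopStart <- st[fin] + finalCodingLen - 3L
  mask <- c(mask, stopStart:(stopStart + 2L))                 # stop codon
  for (i in seq_along(ex)) {
    if (phase[i] == 1L) {                                     # G | AG junction
      mask <- c(mask, en[i - 1L], st[i], st[i] + 1L)
    }
    if (i < length(ex)) {                                     # GT..AG
      mask <- c(mask, en[i] + 1L, en[i] + 2L, st[i + 1L] - 2L, st[i + 1L] - 1L)
    }
  }
  sort(unique(mask))
}

# Per-genomic-position region labels for a model ("intron" between exons).
.regionMapGenomic <- function(model) {
  ex <- model@exons
  kind <- .exonKinds(model)
  phase <- .exonPhases(model)
  lab <- rep("intron", length(model@genomicSeq))
  for (i in seq_along(ex)) {
    idx <- IRanges::start(ex)[i]:IRanges::end(ex)[i]
    reg <- switch(kind[i],
      utr5_signal = , igv = , tm = kind[i],
      "repeat" = "tail", final = "final_exon")
    lab[idx] <- reg
  }
  # refine exon 1 (utr5 vs signal) and the signal-completion nt of exon 2
  e1 <- IRanges::start(ex)[1L]:IRanges::end(ex)[1L]
  lab[e1[seq_len(model@utr5Length)]] <- "utr5"
  lab[setdiff(e1, e1[seq_len(model@utr5Length)])] <- "signal"
  i2 <- which(kind == "igv")
  comp <- (3L - phase[i2]) %% 3L
  if (comp > 0L)
    lab[IRanges::start(ex)[i2]:(IRanges::start(ex)[i2] + comp - 1L)] <- "signal"
  lab
}

# Frame-aware in-place substitution that never creates a stop codon in the
# spliced reading frame. codonOf: genomic pos -> c(codonStart positions) in
# transcript space; we instead check directly on the spliced CDS.
.applySubstitutions <- function(parts, model, rates, mask) {
  genomic <- strsplit(as.character(model@genomicSeq), "")[[1]]
  regmap <- .regionMapGenomic(model)
  # map genomic coding positions -> CDS index, to veto new stop codons
  ex <- model@exons
  kind <- .exonKinds(model)
  cdsIdx <- integer(length(genomic))  # 0 = non-coding
  cds <- character(0)
  pos <- 0L
  for (i in seq_along(ex)) {
    from <- IRanges::start(ex)[i] + if (i == 1L) model@utr5Length else 0L
    to <- IRanges::end(ex)[i]
    if (kind[i] == "final") to <- IRanges::start(ex)[i] + nchar(parts$finalCoding) - 1L
    if (to < from) next
    idx <- from:to
    cdsIdx[idx] <- pos + seq_along(idx)
    pos <- pos + length(idx)
    cds <- c(cds, genomic[idx])
  }
  subs <- data.frame(genomicPos = integer(), region = character(),
                     refBase = character(), altBase = character())
  for (reg in names(rates)) {
    rate <- rates[[reg]]
    if (rate <= 0) next
    cand <- which(regmap == reg)
    cand <- setdiff(cand, mask)
    if (!length(cand)) next
    hit <- cand[stats::runif(length(cand)) < rate]
    for (p in hit) {
      old <- genomic[p]
      new <- .mutateBase(old)
      ci <- cdsIdx[p]
      if (ci > 0L) {
        cstart <- ci - (ci - 1L) %% 3L
        codon <- cds[cstart:(cstart + 2L)]
        codon[ci - cstart + 1L] <- new
        if (.geneticCode()[paste(codon, collapse = "")] == "*") {
          # try the remaining bases; skip the position if all yield stops
          alts <- setdiff(c("A", "C", "G", "T"), c(old, new))
          ok <- FALSE
          for (a in alts) {
            codon[ci - cstart + 1L] <- a
            if (.geneticCode()[paste(codon, collapse = "")] != "*") {
              new <- a; ok <- TRUE; break
            }
          }
          if (!ok) next
        }
        cds[ci] <- new
      }
      genomic[p] <- new
      subs <- rbind(subs, data.frame(genomicPos = p, region = reg,
                                     refBase = old, altBase = new))
    }
  }
  list(genomic = paste(genomic, collapse = ""), substitutions = subs)
}

# Rebuild a GeneModel from an existing one with a replacement genomic string
# of identical layout.
.withGenomic <- function(model, genomic, name = model@name) {
  ex <- model@exons
  GeneModel(name, genomic,
            data.frame(start = IRanges::start(ex), end = IRanges::end(ex),
                       kind = .exonKinds(model), phase = .exonPhases(model)),
            model@utr5Length)
}

#' Simulate a BG-like gene family
#'
#' Generates an ancestral BG gene and derives one gene per entry of
#' `repeatExonCounts` by (i) deleting trailing repeat-exon cassettes or
#' tandemly duplicating an internal cassette to reach the requested count,
#' (ii) rebuilding the final exon to encode the requested number of complete
#' heptads before its stop, and (iii) applying per-region nucleotide
#' substitutions at transition:transversion odds 2:1. Substitutions never
#' touch primer sites, start/stop codons, splice sites or the invariant
#' junction nucleotides, and never create an in-frame stop, so every
#' simulated conceptual transcript translates to its full designed length.
#'
#' @param config A [simulationConfig()].
#' @return A list with elements `genes` (list of [GeneModel], named
#'   `gene1`, `gene2`, ...), `ancestor` (the ancestral [GeneModel]) and
#'   `truth` (per-gene substitution tables and design parameters).
#' @examples
#' fam <- simulateGeneFamily(simulationConfig(seed = 1, repeatExonCounts = c(28L)))
#' nRepeatExons(fam$genes[[1]])
#' @export
simulateGeneFamily <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .withSeed(config$seed, {
    Ranc <- if (is.null(config$ancestorRepeatCount))
      max(config$repeatExonCounts) else config$ancestorRepeatCount
    anc <- .buildGeneParts(Ranc, max(config$stopHeptads),
                           config$intronLengthRange)
    ancestor <- .assembleModel("ancestor", anc)
    genes <- vector("list", length(config$repeatExonCounts))
    truth <- vector("list", length(config$repeatExonCounts))
    for (g in seq_along(config$repeatExonCounts)) {
      Rg <- config$repeatExonCounts[g]
      kg <- config$stopHeptads[g]
      parts <- anc
      repIdx <- which(parts$kinds == "repeat")
      if (Rg < Ranc) {
        drop <- repIdx[(Rg + 1L):Ranc]
        parts$exonSeqs <- parts$exonSeqs[-drop]
        parts$intronSeqs <- parts$intronSeqs[-drop]
        parts$kinds <- parts$kinds[-drop]
        parts$phases <- parts$phases[-drop]
      } else if (Rg > Ranc) {
        dupAt <- if (Ranc > 0L) sample(seq_len(Ranc), 1L) else
          stop("config error: cannot extend a gene with no repeat exons",
               call. = FALSE)
        src <- repIdx[dupAt]
        extra <- Rg - Ranc
        parts$exonSeqs <- append(parts$exonSeqs,
                                 rep(parts$exonSeqs[src], extra), after = src)
        parts$intronSeqs <- append(parts$intronSeqs,
                                   rep(parts$intronSeqs[src], extra), after = src)
        parts$kinds <- append(parts$kinds, rep("repeat", extra), after = src)
        parts$phases <- append(parts$phases, rep(1L, extra), after = src)
      }
      # odd-length repeat exceptions
      if (!is.null(config$oddRepeatLens) &&
          length(config$oddRepeatLens) >= g &&
          !is.null(config$oddRepeatLens[[g]])) {
        odd <- config$oddRepeatLens[[g]]
        repIdx2 <- which(parts$kinds == "repeat")
        for (nm in names(odd)) {
          j <- repIdx2[as.integer(nm)]
          parts$exonSeqs[j] <- .makeRepeatExon(as.integer(odd[[nm]]))
        }
      }
      # final exon for this gene's stop position
      fi <- length(parts$exonSeqs)
      primers <- bgPrimers()
      revSite <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(.resolvePrimer(primers[["UC650"]]))))
      oldFin <- parts$exonSeqs[fi]
      utr3 <- substr(oldFin, nchar(anc$finalCoding) + 1L,
                     nchar(oldFin) - nchar(revSite))
  # reuse ancestral heptad codons, extend/truncate to kg heptads
      ancCodingCodons <- if (max(config$stopHeptads) > 0L)
        substring(anc$finalCoding, seq(3L, nchar(anc$finalCoding) - 3L, by = 3L),
                  seq(5L, nchar(anc$finalCoding) - 1L, by = 3L)) else character(0)
      nNeed <- if (kg > 0L) 7L * kg - 1L else 0L
      codons <- ancCodingCodons[seq_len(min(nNeed, length(ancCodingCodons)))]
      if (length(codons) < nNeed)
        codons <- c(codons, .randomSenseCodons(nNeed - length(codons)))
      finalCoding <- paste0(.JUNC_HEAD, paste(codons, collapse = ""), "TAA")
      fill <- 411L - nchar(finalCoding) - nchar(utr3) - nchar(revSite)
      if (fill > 0L) utr3 <- paste0(utr3, .randomDna(fill))
      if (fill < 0L) utr3 <- substr(utr3, 1L, nchar(utr3) + fill)
      parts$exonSeqs[fi] <- paste0(finalCoding, utr3, revSite)
      parts$finalCoding <- finalCoding
      base <- .assembleModel(sprintf("gene%d", g), parts)
      mut <- .applySubstitutions(parts, base, config$rates,
                                 .immutableMask(base, nchar(finalCoding)))
      genes[[g]] <- .withGenomic(base, mut$genomic)
      truth[[g]] <- mut$substitutions
    }
    names(genes) <- vapply(genes, modelName, character(1L))
    names(truth) <- names(genes)
    list(genes = genes, ancestor = ancestor,
         truth = list(substitutions = truth,
                      repeatExonCounts = config$repeatExonCounts,
                      stopHeptads = config$stopHeptads))
  })
}

# ---- transcripts and clone libraries --------------------------------------

# Spliced transcript of a model with the given introns retained
# (intron i follows exon i). Returns list(seq, map = data.frame of
# transcript segments with labels).
.spliceTranscript <- function(model, retained = integer(0)) {
  exSeqs <- .exonSeqs(model)
  inSeqs <- .intronSeqs(model)
  segs <- list()
  seq <- character(0)
  pos <- 0L
  for (i in seq_along(exSeqs)) {
    w <- nchar(exSeqs[i])
    segs[[length(segs) + 1L]] <- data.frame(
      start = pos + 1L, end = pos + w,
      label = sprintf("exon %d", i), kind = "exon", exonIndex = i)
    seq <- c(seq, exSeqs[i]); pos <- pos + w
    if (i %in% retained) {
      wi <- nchar(inSeqs[i])
      segs[[length(segs) + 1L]] <- data.frame(
        start = pos + 1L, end = pos + wi,
        label = sprintf("retained-intron after exon %d", i),
        kind = "retained_intron", exonIndex = i)
      seq <- c(seq, inSeqs[i]); pos <- pos + wi
    }
  }
  list(seq = paste(seq, collapse = ""), map = do.call(rbind, segs))
}

# Per-position region labels of a spliced transcript (no retained introns).
.transcriptRegionMap <- function(model) {
  regmap <- .regionMapGenomic(model)
  ex <- model@exons
  idx <- unlist(lapply(seq_along(ex), function(i)
    IRanges::start(ex)[i]:IRanges::end(ex)[i]))
  regmap[idx]
}

#' Simulate a cDNA clone library with ground truth
#'
#' Emits `cloneDepth` clones per gene. Each clone is a nearly full-length
#' transcript bounded by the forward/reverse primer sites; each intron is
#' retained independently with probability `intronRetentionProb`. Planted
#' artefacts: `chimeraCount` single-crossover chimeras between two parent
#' transcripts (breakpoint uniform within the Ig-V exon or the tail), and
#' `singletonErrorCount` clones carrying one extra substitution in the Ig-V
#' region, each present exactly once in a single PCR batch (emulating
#' nucleotide mis-incorporation during amplification).
#'
#' @param genes List of [GeneModel] (e.g. from [simulateGeneFamily()]).
#' @param config A [simulationConfig()].
#' @return List with elements `library` (a [CloneLibrary]) and `truth`
#'   (`data.frame`, one row per clone: source gene, retained introns,
#'   chimera parents/breakpoint, singleton-error flag and position).
#' @export
simulateCloneLibrary <- function(genes, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (length(genes) == 0L) stop("input error: empty gene list", call. = FALSE)
  .withSeed(config$seed + 500009L, {
    seqs <- character(0); ids <- character(0)
    batch <- character(0)
    truth <- list()
    depth <- rep_len(config$cloneDepth, length(genes))
    for (g in seq_along(genes)) {
      model <- genes[[g]]
      nIntrons <- length(model@exons) - 1L
      for (d in seq_len(depth[g])) {
        retained <- which(stats::runif(nIntrons) < config$intronRetentionProb)
        tr <- .spliceTranscript(model, retained)
        id <- sprintf("%s_%s_c%02d", config$line, modelName(model), d)
        ids <- c(ids, id); seqs <- c(seqs, tr$seq)
        batch <- c(batch, sprintf("PCR%d", sample.int(config$nBatches, 1L)))
        truth[[length(truth) + 1L]] <- data.frame(
          clone_id = id, gene = modelName(model),
          retained_introns = paste(retained, collapse = ","),
          is_chimera = FALSE, chimera_parents = "", chimera_breakpoint = NA_integer_,
          is_singleton_error = FALSE, error_pos = NA_integer_)
      }
    }
    # chimeras: single crossover between two spliced parent transcripts
    if (config$chimeraCount > 0L && length(genes) < 2L)
      stop("input error: chimeras need at least two genes", call. = FALSE)
    for (ch in seq_len(config$chimeraCount)) {
      pg <- sample.int(length(genes), 2L)
      ta <- .spliceTranscript(genes[[pg[1L]]])$seq
      tb <- .spliceTranscript(genes[[pg[2L]]])$seq
      mapA <- .transcriptRegionMap(genes[[pg[1L]]])
      mapB <- .transcriptRegionMap(genes[[pg[2L]]])
      reg <- sample(c("igv", "tail"), 1L)
      inA <- which(mapA == reg)
      offA <- sample.int(length(inA), 1L)
      bpA <- inA[offA]
      inB <- which(mapB == reg)
      bpB <- inB[min(offA, length(inB))]
      child <- paste0(substr(ta, 1L, bpA), substr(tb, bpB + 1L, nchar(tb)))
      id <- sprintf("%s_chimera_%02d", config$line, ch)
      ids <- c(ids, id); seqs <- c(seqs, child)
      batch <- c(batch, sprintf("PCR%d", sample.int(config$nBatches, 1L)))
      truth[[length(truth) + 1L]] <- data.frame(
        clone_id = id, gene = NA_character_, retained_introns = "",
        is_chimera = TRUE,
        chimera_parents = paste(modelName(genes[[pg[1L]]]),
                                modelName(genes[[pg[2L]]]), sep = "+"),
        chimera_breakpoint = bpA,
        is_singleton_error = FALSE, error_pos = NA_integer_)
    }
    # singleton mis-incorporation errors: one extra Ig-V substitution,
    # present in exactly one clone in one PCR batch
    for (e in seq_len(config$singletonErrorCount)) {
      g <- sample.int(length(genes), 1L)
      model <- genes[[g]]
      tr <- .spliceTranscript(model)
      map <- .transcriptRegionMap(model)
      cand <- which(map == "igv")
      chars <- strsplit(tr$seq, "")[[1]]
      codingStart <- model@utr5Length + 1L
      repeat {
        p <- sample(cand, 1L)
        new <- .mutateBase(chars[p])
        cstart <- p - (p - codingStart) %% 3L
        trial <- chars; trial[p] <- new
        codon <- paste(trial[cstart:(cstart + 2L)], collapse = "")
        if (!codon %in% .stopCodons) break
      }
      chars[p] <- new
      id <- sprintf("%s_err_%02d", config$line, e)
      ids <- c(ids, id); seqs <- c(seqs, paste(chars, collapse = ""))
      batch <- c(batch, sprintf("PCR%d", sample.int(config$nBatches, 1L)))
      truth[[length(truth) + 1L]] <- data.frame(
        clone_id = id, gene = modelName(model), retained_introns = "",
        is_chimera = FALSE, chimera_parents = "", chimera_breakpoint = NA_integer_,
        is_singleton_error = TRUE, error_pos = p)
    }
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- ids
    meta <- data.frame(clone_id = ids, line = config$line,
                       pcr_batch = batch, n_observed = 1L,
                       stringsAsFactors = FALSE)
    list(library = methods::new("CloneLibrary", seqs = dna, meta = meta),
         truth = do.call(rbind, truth))
  })
}

# ---- CloneLibrary plumbing ------------------------------------------------

#' @rdname CloneLibrary-class
#' @param seqs A named [Biostrings::DNAStringSet].
#' @param meta `data.frame` with columns `clone_id`, `line`, `pcr_batch`,
#'   `n_observed`; defaults are filled in when omitted.
#' @export
CloneLibrary <- function(seqs, meta = NULL) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("clone%03d", seq_along(seqs))
  if (is.null(meta))
    meta <- data.frame(clone_id = names(seqs), line = "?",
                       pcr_batch = "PCR1", n_observed = 1L,
                       stringsAsFactors = FALSE)
  meta <- meta[match(names(seqs), meta$clone_id), , drop = FALSE]
  rownames(meta) <- NULL
  methods::new("CloneLibrary", seqs = seqs, meta = meta)
}

#' @rdname CloneLibrary-class
#' @export
setMethod("cloneSeqs", "CloneLibrary", function(x) x@seqs)
#' @rdname CloneLibrary-class
#' @export
setMethod("cloneMeta", "CloneLibrary", function(x) x@meta)

setMethod("show", "CloneLibrary", function(object) {
  cat("CloneLibrary with", length(object@seqs), "clones from line(s)",
      paste(unique(object@meta$line), collapse = ", "), "\n")
})

#' Write / read a clone library (FASTA + metadata TSV)
#'
#' @param lib A [CloneLibrary].
#' @param dir Output directory (created if needed); files `clones.fasta`
#'   and `clones.tsv` are written.
#' @return The directory, invisibly.
#' @export
writeCloneLibrary <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(cloneSeqs(lib), file.path(dir, "clones.fasta"))
  utils::write.table(cloneMeta(lib), file.path(dir, "clones.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCloneLibrary
#' @param fasta,tsv Paths to the clone FASTA and metadata TSV (`tsv` may be
#'   `NULL`, in which case default metadata are synthesised).
#' @export
readCloneLibrary <- function(fasta, tsv = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  meta <- if (!is.null(tsv))
    utils::read.delim(tsv, stringsAsFactors = FALSE) else NULL
  CloneLibrary(seqs, meta)
}
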