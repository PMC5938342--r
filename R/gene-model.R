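#' Construct a BG gene model
#'
#' Builds and validates a [GeneModel] from a genomic sequence and an exon
#' table. Exon coordinates are 1-based and closed on the genomic sequence;
#' the JSON interchange format written by [writeGeneModel()] uses 0-based
#' half-open coordinates instead (converted at the boundary, like GFF3's
#' 1-based inclusive convention).
#'
#' @param name Gene identifier.
#' @param genomicSeq Genomic sequence (character or [Biostrings::DNAString]).
#' @param exons `data.frame` with columns `start`, `end` (1-based closed),
#'   `kind` and `phase`.
#' @param utr5Length Number of 5'UTR nucleotides at the start of exon 1.
#' @return A validated [GeneModel].
#' @examples
#' gm <- canonicalGeneModel()
#' gm
#' @export
GeneModel <- function(name, genomicSeq, exons, utr5Length) {
  ir <- IRanges::IRanges(start = as.integer(exons$start), end = as.integer(exons$end))
  S4Vectors::mcols(ir) <- S4Vectors::DataFrame(
    kind = as.character(exons$kind),
    phase = as.integer(exons$phase)
  )
  methods::new("GeneModel",
    name = as.character(name),
    genomicSeq = Biostrings::DNAString(as.character(genomicSeq)),
    exons = ir,
    utr5Length = as.integer(utr5Length)
  )
}

#' @rdname GeneModel-class
#' @export
setMethod("modelName", "GeneModel", function(x) x@name)
#' @rdname GeneModel-class
#' @export
setMethod("genomicSeq", "GeneModel", function(x) x@genomicSeq)
#' @rdname GeneModel-class
#' @export
setMethod("modelExons", "GeneModel", function(x) x@exons)
#' @rdname GeneModel-class
#' @export
setMethod("utr5Length", "GeneModel", function(x) x@utr5Length)

setMethod("show", "GeneModel", function(object) {
  kind <- .exonKinds(object)
  cat("GeneModel", object@name, "\n")
  cat("  genomic length:", length(object@genomicSeq), "nt;",
      length(object@exons), "exons (", sum(kind == "repeat"),
      "repeat exons )\n")
  rl <- regionLengths(object)
  cat("  regions:",
      paste(sprintf("%s=%dnt", rl$region, rl$nt), collapse = " "), "\n")
})

#' Number of repeat exons in a model
#' @param model A [GeneModel].
#' @return Integer count of repeat exons.
#' @export
nRepeatExons <- function(model) sum(.exonKinds(model) == "repeat")

#' Region lengths of a gene model
#'
#' Nucleotide (and where applicable amino-acid) extent of each mRNA region.
#' Boundary nucleotides follow the exon layout: the first two nucleotides of
#' exon 2 complete the final split codon of the signal sequence and are
#' counted as signal, so for the canonical architecture the signal is
#' 99 nt / 33 aa and the Ig-V domain 342 nt / 114 aa; the final exon is
#' counted whole (its few coding nucleotides plus the 3'UTR).
#'
#' @param model A [GeneModel].
#' @return `data.frame` with columns `region`, `nt`, `aa`.
#' @export
regionLengths <- function(model) {
  w <- IRanges::width(model@exons)
  kind <- .exonKinds(model)
  phase <- .exonPhases(model)
  completion2 <- (3L - phase[which(kind == "igv")]) %% 3L
  signal_nt <- (w[1L] - model@utr5Length) + completion2
  igv_nt <- w[which(kind == "igv")] - completion2
  tail_nt <- sum(w[kind == "repeat"])
  data.frame(
    region = c("utr5", "signal", "igv", "tm", "tail", "final_exon"),
    nt = as.integer(c(model@utr5Length, signal_nt, igv_nt,
                      w[which(kind == "tm")], tail_nt,
                      w[which(kind == "final")])),
    aa = as.integer(c(NA, signal_nt %/% 3L, igv_nt %/% 3L,
                      w[which(kind == "tm")] %/% 3L, tail_nt %/% 3L, NA)),
    stringsAsFactors = FALSE
  )
}

#' Protein region encoded by an exon
#'
#' Maps an exon of the canonical BG architecture to the mRNA/protein region
#' it encodes: exon 1 carries the 5'UTR and the signal sequence, exon 2 the
#' Ig-V domain, exon 3 the TM region, the 21-nt repeat exons the cytoplasmic
#' tail, and the final exon the last tail residues plus the 3'UTR.
#'
#' @param model A [GeneModel].
#' @param exonIndex 1-based exon number.
#' @return Character vector of region labels (two for the composite exons).
#' @examples
#' regionOf(canonicalGeneModel(), 2)  # "Ig-V"
#' @export
regionOf <- function(model, exonIndex) {
  kind <- .exonKinds(model)
  if (exonIndex < 1L || exonIndex > length(kind))
    stop("exonIndex out of range", call. = FALSE)
  switch(kind[exonIndex],
    utr5_signal = c("5'UTR", "signal"),
    igv = "Ig-V",
    tm = "TM",
    "repeat" = "cytoplasmic tail",
    final = c("tail-terminal", "3'UTR")
  )
}

# ---- model I/O ------------------------------------------------------------

.modelToList <- function(model) {
  ex <- model@exons
  list(
    name = model@name,
    genomic_seq = as.character(model@genomicSeq),
    utr5_length = model@utr5Length,
    exons = lapply(seq_along(ex), function(i) list(
      index = i,
      kind = .exonKinds(model)[i],
      # JSON dialect: 0-based half-open
      genomic_start = IRanges::start(ex)[i] - 1L,
      genomic_end = IRanges::end(ex)[i],
      phase = .exonPhases(model)[i]
    ))
  )
}

.modelFromList <- function(x, path = "<json>") {
  need <- c("name", "genomic_seq", "utr5_length", "exons")
  if (!all(need %in% names(x)))
    stop("malformed gene model in ", path, ": missing ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  exdf <- do.call(rbind, lapply(x$exons, function(e) {
    if (as.integer(e$genomic_end) <= as.integer(e$genomic_start))
      stop("validation error in ", path, ": exon ", e$index,
           " has end <= start", call. = FALSE)
    data.frame(
      start = as.integer(e$genomic_start) + 1L,  # 0-based half-open -> 1-based closed
      end = as.integer(e$genomic_end),
      kind = as.character(e$kind),
      phase = as.integer(e$phase)
    )
  }))
  GeneModel(x$name, x$genomic_seq, exdf, x$utr5_length)
}

#' Read a gene model from disk
#'
#' Two dialects are supported: the package's JSON interchange format
#' (0-based half-open exon coordinates), and FASTA + GFF3 (1-based inclusive
#' coordinates, converted internally). GFF3 exon features must carry `kind`
#' and `phase_prev` attributes and, for exon 1, `utr5_length`.
#'
#' @param path Path to the JSON model or the GFF3 file.
#' @param format `"json"` or `"fasta+gff3"`.
#' @param fasta For `"fasta+gff3"`, path to the genomic FASTA.
#' @return A validated [GeneModel] (or a list of them when the JSON file
#'   holds several models).
#' @seealso [writeGeneModel()]
#' @export
loadGeneModel <- function(path, format = c("json", "fasta+gff3"), fasta = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    x <- tryCatch(jsonlite::read_json(path),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    if (!is.null(x$name)) return(.modelFromList(x, path))
    return(lapply(x, .modelFromList, path = path))
  }
  if (is.null(fasta))
    stop("format 'fasta+gff3' requires the 'fasta' argument", call. = FALSE)
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("loading FASTA+GFF3 models requires the rtracklayer package",
         call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L)
    stop("no exon features in ", path, call. = FALSE)
  start <- IRanges::start(gr); end <- IRanges::end(gr)
  if (any(end < start))
    stop("validation error in ", path, ": exon end < start", call. = FALSE)
  kind <- as.character(gr$kind)
  phase <- as.integer(gr$phase_prev)
  utr5 <- suppressWarnings(as.integer(gr$utr5_length))
  utr5 <- utr5[!is.na(utr5)][1L]
  if (is.na(utr5)) stop("GFF3 exon 1 must carry a utr5_length attribute",
                        call. = FALSE)
  seqid <- as.character(gr@seqnames)[1L]
  if (!seqid %in% names(seqs))
    stop("sequence ", seqid, " not found in ", fasta, call. = FALSE)
  ord <- order(start)
  GeneModel(seqid, as.character(seqs[[seqid]]),
            data.frame(start = start[ord], end = end[ord],
                       kind = kind[ord], phase = phase[ord]),
            utr5)
}

#' Write a gene model (or list of models) as JSON
#'
#' @param model A [GeneModel] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneModel <- function(model, path) {
  x <- if (methods::is(model, "GeneModel")) .modelToList(model)
       else lapply(model, .modelToList)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write per-gene exon structure as GFF3 (+ FASTA)
#'
#' Emits the exon layout of one or more models in GFF3 (1-based inclusive)
#' with `kind`/`phase_prev`/`utr5_length` attributes, and the genomic
#' sequences as FASTA, so that [loadGeneModel()] round-trips them.
#'
#' @param models A [GeneModel] or list of them.
#' @param gffPath,fastaPath Output paths.
#' @return `gffPath`, invisibly.
#' @export
writeGeneModelGff3 <- function(models, gffPath, fastaPath) {
  if (methods::is(models, "GeneModel")) models <- list(models)
  lines <- "##gff-version 3"
  for (m in models) {
    ex <- m@exons
    for (i in seq_along(ex)) {
      attrs <- sprintf("ID=%s.exon%d;kind=%s;phase_prev=%d",
                       m@name, i, .exonKinds(m)[i], .exonPhases(m)[i])
      if (i == 1L) attrs <- paste0(attrs, ";utr5_length=", m@utr5Length)
      lines <- c(lines, paste(m@name, "bgalleles", "exon",
                              IRanges::start(ex)[i], IRanges::end(ex)[i],
                              ".", "+", ".", attrs, sep = "\t"))
    }
  }
  writeLines(lines, gffPath)
  seqs <- Biostrings::DNAStringSet(vapply(models, function(m)
    as.character(m@genomicSeq), character(1L)))
  names(seqs) <- vapply(models, function(m) m@name, character(1L))
  Biostrings::writeXStringSet(seqs, fastaPath)
  invisible(gffPath)
}

# ---- primers --------------------------------------------------------------

#' Locate degenerate primer sites in a sequence
#'
#' Finds every occurrence of an IUPAC primer (or its reverse complement) in a
#' DNA sequence, allowing up to `maxMismatch` mismatches under IUPAC-aware
#' comparison (N matches anything, R matches A/G, and so on). Coordinates are
#' 1-based and closed on the input sequence; minus-strand hits are reported
#' in plus-strand coordinates.
#'
#' @param seq Subject sequence (character or [Biostrings::DNAString]).
#' @param primer IUPAC primer sequence, length >= 10.
#' @param maxMismatch Maximum number of mismatching positions (default 0).
#' @return `data.frame` with columns `start`, `end`, `strand`, `mismatches`,
#'   sorted by `start`.
#' @examples
#' findPrimerSites("GGTAACACCCAAAGCAGTTTTCTACCGG",
#'                 "TAACACCCAAAGCAGTTTTCTNCC")
#' @export
findPrimerSites <- function(seq, primer, maxMismatch = 0L) {
  primer <- toupper(primer)
  if (!.isIUPAC(primer))
    stop("primer contains non-IUPAC characters", call. = FALSE)
  if (nchar(primer) < 10L) stop("primer must be >= 10 nt", call. = FALSE)
  if (maxMismatch < 0L) stop("maxMismatch must be >= 0", call. = FALSE)
  subject <- Biostrings::DNAString(as.character(seq))
  scan1 <- function(pat, strand) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                     max.mismatch = maxMismatch, fixed = FALSE)
    if (length(hits) == 0L) return(NULL)
    mm <- vapply(seq_along(hits), function(i) {
      .iupacMismatches(pat, as.character(hits[[i]]))
    }, integer(1L))
    data.frame(start = IRanges::start(hits), end = IRanges::end(hits),
               strand = strand, mismatches = mm, stringsAsFactors = FALSE)
  }
  rcomp <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(primer)))
  out <- rbind(scan1(primer, "+"), scan1(rcomp, "-"))
  if (is.null(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# IUPAC-aware mismatch count between a (possibly degenerate) pattern and an
# equal-length ACGT window.
.iupacMismatches <- function(pattern, window) {
  pc <- strsplit(pattern, "")[[1]]
  wc <- strsplit(window, "")[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  sum(!mapply(function(p, w) grepl(w, map[[p]], fixed = TRUE), pc, wc))
}

#' Primer sequences used for BG cDNA amplification
#'
#' The published primer set: H forward (UC206) and U reverse (UC650) amplify
#' nearly full-length transcripts (5'UTR to 3'UTR); SS forward (UC74) and TM
#' reverse (UC76) amplify signal sequence to transmembrane region.
#'
#' @return Named character vector of IUPAC primer sequences.
#' @export
bgPrimers <- function() {
  c(UC206 = "TCCGCTCGAGCTCTCTYCTCCTACAG",
    UC650 = "TAACACCCAAAGCAGTTTTCTNCC",
    UC74 = "CTCCTGCCTTATCTCRTGGCTCTGCAC",
    UC76 = "CACAGCCAGAGCCACYKTCCAG")
}
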