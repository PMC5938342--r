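#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet AAString
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Canonical BG gene architecture
#'
#' A `GeneModel` holds the genomic sequence of one BG gene together with its
#' ordered exon layout. BG genes share a stereotyped architecture: exon 1
#' carries the 5'UTR and the signal sequence, exon 2 the extracellular Ig-V
#' domain, exon 3 the transmembrane (TM) region, then a variable number of
#' short repeat exons (canonically 21 nt, occasionally 18 or 24 nt) encoding
#' the heptad repeats of the cytoplasmic tail, and a final exon holding the
#' last coding nucleotides and the 3'UTR. All repeat exons are phase 1: the
#' first codon of each repeat unit is split, one nucleotide coming from the
#' previous exon and two from the exon under consideration.
#'
#' @slot name Gene identifier.
#' @slot genomicSeq [Biostrings::DNAString] of the gene's genomic sequence.
#' @slot exons [IRanges::IRanges] of exon coordinates on `genomicSeq`
#'   (1-based, closed), with metadata columns `kind` (one of
#'   `"utr5_signal"`, `"igv"`, `"tm"`, `"repeat"`, `"final"`) and `phase`
#'   (0--2, the number of nucleotides of the boundary-split codon contributed
#'   by the previous exon).
#' @slot utr5Length Number of 5'UTR nucleotides at the start of exon 1
#'   (everything before the ATG), including any primer-binding site.
#'
#' @seealso [GeneModel()], [canonicalGeneModel()], [loadGeneModel()]
#' @export
setClass("GeneModel",
  representation(
    name = "character",
    genomicSeq = "DNAString",
    exons = "IRanges",
    utr5Length = "integer"
  )
)

.validGeneModel <- function(object) {
  msgs <- character()
  ex <- object@exons
  kind <- S4Vectors::mcols(ex)$kind
  phase <- S4Vectors::mcols(ex)$phase
  if (is.null(kind) || is.null(phase))
    return("exons must carry 'kind' and 'phase' metadata columns")
  if (length(ex) < 4L)
    msgs <- c(msgs, "a BG model needs at least utr5_signal, igv, tm and final exons")
  if (any(IRanges::width(ex) < 1L))
    msgs <- c(msgs, "all exons must satisfy start <= end")
  st <- IRanges::start(ex); en <- IRanges::end(ex)
  if (is.unsorted(st, strictly = TRUE))
    msgs <- c(msgs, "exons must be strictly ordered by start")
  if (length(ex) > 1L && any(st[-1L] <= en[-length(ex)]))
    msgs <- c(msgs, "exons must not overlap")
  for (k in c("utr5_signal", "igv", "tm", "final"))
    if (sum(kind == k) != 1L)
      msgs <- c(msgs, sprintf("exactly one exon of kind '%s' required", k))
  rep_w <- IRanges::width(ex)[kind == "repeat"]
  if (length(rep_w) && !all(rep_w %in% c(18L, 21L, 24L)))
    msgs <- c(msgs, "repeat exons must be 18, 21 or 24 nt")
  if (any(kind == "repeat") && !all(phase[kind == "repeat"] == 1L))
    msgs <- c(msgs, "repeat exons must be phase 1")
  ord <- match(c("utr5_signal", "igv", "tm"), kind)
  if (!any(is.na(ord)) && is.unsorted(ord))
    msgs <- c(msgs, "exon kinds must occur in order utr5_signal, igv, tm, repeat..., final")
  if (kind[length(kind)] != "final")
    msgs <- c(msgs, "the final exon must come last")
  if (max(en) > length(object@genomicSeq))
    msgs <- c(msgs, "exon coordinates exceed the genomic sequence")
  if (object@utr5Length < 0L || object@utr5Length >= IRanges::width(ex)[1L])
    msgs <- c(msgs, "utr5Length must be non-negative and smaller than exon 1")
  if (length(msgs)) msgs else TRUE
}
setValidity("GeneModel", .validGeneModel)

#' A set of sequenced cDNA clones with PCR provenance
#'
#' Container pairing clone sequences with their metadata: the chicken line
#' each clone came from, the PCR batch it was amplified in, and the number of
#' identical copies observed. Clones are Sanger-finished sequences; IUPAC
#' ambiguity codes are only tolerated within primer-binding sites.
#'
#' @slot seqs [Biostrings::DNAStringSet] named by clone id.
#' @slot meta `data.frame` with columns `clone_id`, `line`, `pcr_batch`,
#'   `n_observed`, one row per clone, in the order of `seqs`.
#'
#' @seealso [CloneLibrary()], [simulateCloneLibrary()], [readCloneLibrary()]
#' @export
setClass("CloneLibrary",
  representation(seqs = "DNAStringSet", meta = "data.frame")
)

setValidity("CloneLibrary", function(object) {
  msgs <- character()
  need <- c("clone_id", "line", "pcr_batch", "n_observed")
  if (!all(need %in% names(object@meta)))
    msgs <- c(msgs, paste("meta must have columns", paste(need, collapse = ", ")))
  else {
    if (nrow(object@meta) != length(object@seqs))
      msgs <- c(msgs, "meta must have one row per sequence")
    else if (!identical(as.character(object@meta$clone_id), names(object@seqs)))
      msgs <- c(msgs, "meta$clone_id must match names(seqs) in order")
    if (any(object@meta$n_observed < 1L))
      msgs <- c(msgs, "n_observed must be positive")
  }
  if (any(Biostrings::width(object@seqs) == 0L))
    msgs <- c(msgs, "clone sequences must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' Per-clone segmentation, translation and splice interpretation
#'
#' The result of annotating one cDNA clone against a [GeneModel]: the tiling
#' of the clone into exon segments and retained introns, the conceptual
#' coding sequence (exons only) and the actual coding sequence (with retained
#' introns), both translations, the position of the first in-frame stop, and
#' per-codon provenance used downstream for heptad-register assignment and
#' split-codon accounting.
#'
#' @slot cloneId Clone identifier.
#' @slot modelName Name of the best-matching [GeneModel].
#' @slot unassignable `TRUE` when no model exon reached the identity
#'   threshold; such clones are excluded from grouping.
#' @slot cloneSeq The clone sequence as a [Biostrings::DNAString].
#' @slot segments `data.frame` tiling the clone: `start`, `end` (1-based,
#'   closed clone coordinates), `label`, `kind` (`"exon"`,
#'   `"retained_intron"` or `"unaligned"`), `exonIndex`, `identity`.
#' @slot conceptualCds,actualCds Coding sequence from the signal-sequence ATG
#'   to the end of the clone, excluding/including retained introns.
#' @slot proteinConceptual,proteinActual Translations up to (not including)
#'   the first in-frame stop.
#' @slot stopConceptual,stopActual Lists `list(label=, offset=)` locating the
#'   first in-frame stop codon in segment coordinates (offset of its first
#'   nucleotide within the named segment, 1-based), or empty when no stop was
#'   reached.
#' @slot codonsConceptual,codonsActual Per-codon provenance tables with
#'   columns `codon`, `aa`, `exonIndex`, `region`, `unitIndex`, `codonPos`
#'   (position 1--7 within a cytoplasmic-tail repeat unit, `NA` elsewhere),
#'   `translated`.
#' @slot retainedIntrons Labels of retained-intron segments.
#' @slot tailLengthAa Number of translated residues after the TM region in
#'   the actual transcript.
#' @slot extraRepeats Number of repeat-exon copies found in the clone beyond
#'   the model's inventory (tandem insertions).
#'
#' @seealso [annotateClone()], [countApparentHeptads()],
#'   [conceptualTranscript()]
#' @export
setClass("TranscriptAnnotation",
  representation(
    cloneId = "character",
    modelName = "character",
    unassignable = "logical",
    cloneSeq = "DNAString",
    segments = "data.frame",
    conceptualCds = "DNAString",
    actualCds = "DNAString",
    proteinConceptual = "AAString",
    proteinActual = "AAString",
    stopConceptual = "list",
    stopActual = "list",
    codonsConceptual = "data.frame",
    codonsActual = "data.frame",
    retainedIntrons = "character",
    tailLengthAa = "integer",
    extraRepeats = "integer"
  )
)

#' A putative gene: clones sharing one exon-2 sequence
#'
#' Clones whose exon-2 (Ig-V) sequences are exactly identical are taken to
#' originate from the same gene. Within a chicken line, groups are lettered
#' by abundance ("a" = most clones) and splice variants within a group are
#' numbered by abundance ("1" = most clones), following the field's
#' convention for naming BG transcripts.
#'
#' @slot line Chicken line identifier.
#' @slot exon2Seq The shared exon-2 sequence (character).
#' @slot letter Group letter within the line ("a", "b", ...).
#' @slot cloneIds Identifiers of member clones.
#' @slot variants `data.frame` with columns `variant` (number),
#'   `representative` (clone id), `sequence`, `nClones`, `nBatches`,
#'   ordered by descending clone count.
#' @slot flags Subset of `"possible_misincorporation"`,
#'   `"chimeric_members_removed"`, `"single_pcr_only"`, `"letter_only"`.
#'
#' @seealso [groupByExon2()], [flagSingletons()], [nameSequences()]
#' @export
setClass("GeneGroup",
  representation(
    line = "character",
    exon2Seq = "character",
    letter = "character",
    cloneIds = "character",
    variants = "data.frame",
    flags = "character"
  )
)

setValidity("GeneGroup", function(object) {
  if (nrow(object@variants) &&
      anyDuplicated(object@variants$variant[!is.na(object@variants$variant)]))
    return("variant numbers must be unique within a group")
  TRUE
})
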