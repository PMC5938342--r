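#' @rdname GeneModel-class
#' @param object,x A `GeneModel`.
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname GeneModel-class
#' @export
setGeneric("genomicSeq", function(x) standardGeneric("genomicSeq"))

#' @rdname GeneModel-class
#' @export
setGeneric("modelExons", function(x) standardGeneric("modelExons"))

#' @rdname GeneModel-class
#' @export
setGeneric("utr5Length", function(x) standardGeneric("utr5Length"))

#' @rdname CloneLibrary-class
#' @param x A `CloneLibrary`.
#' @export
setGeneric("cloneSeqs", function(x) standardGeneric("cloneSeqs"))

#' @rdname CloneLibrary-class
#' @export
setGeneric("cloneMeta", function(x) standardGeneric("cloneMeta"))

#' @rdname TranscriptAnnotation-class
#' @param x A `TranscriptAnnotation`.
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname TranscriptAnnotation-class
#' @export
setGeneric("retainedIntrons", function(x) standardGeneric("retainedIntrons"))

#' @rdname TranscriptAnnotation-class
#' @export
setGeneric("tailLengthAa", function(x) standardGeneric("tailLengthAa"))

#' Conceptual transcript of an annotated clone
#'
#' Concatenates the exon segments of a clone in order, dropping retained
#' introns and unaligned flanks. This is the "exons without introns"
#' reconstruction used throughout the analysis; it is idempotent in the
#' sense that re-annotating the result yields the same transcript.
#'
#' @param x A [TranscriptAnnotation].
#' @return A [Biostrings::DNAString].
#' @export
setGeneric("conceptualTranscript", function(x) standardGeneric("conceptualTranscript"))
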