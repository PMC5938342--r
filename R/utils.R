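# Internal helpers shared across modules.

# Sense codons of the standard (vertebrate nuclear) genetic code.
.geneticCode <- function() Biostrings::GENETIC_CODE
.stopCodons <- c("TAA", "TAG", "TGA")
.senseCodons <- function() {
  gc <- .geneticCode()
  names(gc)[gc != "*"]
}

.translateCodons <- function(codons) {
  unname(.geneticCode()[codons])
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.isIUPAC <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  all(chars %in% names(Biostrings::IUPAC_CODE_MAP))
}

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random sense codons; first can be forced to ATG.
.randomSenseCodons <- function(n) {
  sample(.senseCodons(), n, replace = TRUE)
}

# Transition partner of each base (A<->G, C<->T).
.transition <- c(A = "G", G = "A", C = "T", T = "C")
.transversions <- list(
  A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G")
)

# Draw a substitute base at transition:transversion odds 2:1.
.mutateBase <- function(base) {
  if (stats::runif(1) < 2 / 3) .transition[[base]]
  else sample(.transversions[[base]], 1L)
}

.exonKinds <- function(model) S4Vectors::mcols(model@exons)$kind
.exonPhases <- function(model) S4Vectors::mcols(model@exons)$phase

# Exon sequences of a model as a character vector.
.exonSeqs <- function(model) {
  ex <- model@exons
  vapply(seq_along(ex), function(i) {
    as.character(Biostrings::subseq(model@genomicSeq,
      IRanges::start(ex)[i], IRanges::end(ex)[i]))
  }, character(1L))
}

# Intron sequences (gaps between consecutive exons).
.intronSeqs <- function(model) {
  ex <- model@exons
  n <- length(ex)
  if (n < 2L) return(character(0L))
  vapply(seq_len(n - 1L), function(i) {
    s <- IRanges::end(ex)[i] + 1L
    e <- IRanges::start(ex)[i + 1L] - 1L
    if (e < s) "" else as.character(Biostrings::subseq(model@genomicSeq, s, e))
  }, character(1L))
}

# Per-exon coding widths: exon 1 contributes everything after the 5'UTR,
# other exons contribute their full width except the untranslated remainder
# of the final exon, which is handled by translation stopping at the stop.
.codingWidths <- function(model) {
  w <- IRanges::width(model@exons)
  w[1L] <- w[1L] - model@utr5Length
  w
}

.hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Needleman-Wunsch on arbitrary "blocks" with a user score function.
# Returns a two-column matrix of indices (i in a, j in b), NA = gap.
# Used for whole-heptad / whole-exon alignment where gaps are only
# allowed in complete units.
.blockNW <- function(a, b, score, gap = -4) {
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  P <- matrix(0L, n + 1L, m + 1L)  # 1 diag, 2 up (gap in b), 3 left (gap in a)
  P[, 1L] <- 2L; P[1L, ] <- 3L; P[1L, 1L] <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- S[i, j] + score(a[[i]], b[[j]])
      u <- S[i, j + 1L] + gap
      l <- S[i + 1L, j] + gap
      best <- max(d, u, l)
      S[i + 1L, j + 1L] <- best
      P[i + 1L, j + 1L] <- if (best == d) 1L else if (best == u) 2L else 3L
    }
  }
  path <- matrix(NA_integer_, 0L, 2L)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    p <- P[i + 1L, j + 1L]
    if (p == 1L) { path <- rbind(c(i, j), path); i <- i - 1L; j <- j - 1L }
    else if (p == 2L) { path <- rbind(c(i, NA), path); i <- i - 1L }
    else { path <- rbind(c(NA, j), path); j <- j - 1L }
  }
  colnames(path) <- c("i", "j")
  path
}
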