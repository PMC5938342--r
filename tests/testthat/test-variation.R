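# Plant a specific codon into the Ig-V exon of a gene (genomic surgery on
# a zero-rate simulated gene). codonInIgv is 1-based among the 114 complete
# Ig-V codons, whose first nt sits 2 nt into exon 2.
plantIgvCodon <- function(gene, codonInIgv, codon) {
  ex <- modelExons(gene)
  e2 <- IRanges::start(ex)[2]
  at <- e2 + 2L + 3L * (codonInIgv - 1L)
  g <- as.character(genomicSeq(gene))
  substr(g, at, at + 2L) <- codon
  bgalleles:::.withGenomic(gene, g)
}

basePair <- function(seed = 401) {
  cfg <- simulationConfig(seed = seed, repeatExonCounts = 5L,
                          stopHeptads = 1L, rates = zeroRates)
  simulateGeneFamily(cfg)$genes[[1]]
}

annotOf <- function(gene, id = "x")
  annotateClone(spliceModel(gene), gene, cloneId = id)

test_that("single-nucleotide codon changes classify by the genetic code", {
  g <- basePair()
  ref <- plantIgvCodon(g, 10, "GCA")
  silent <- plantIgvCodon(ref, 10, "GCC")      # Ala -> Ala
  refK <- plantIgvCodon(g, 10, "AAA")
  repl <- plantIgvCodon(refK, 10, "GAA")       # Lys -> Glu
  cr <- compareRegions(annotOf(ref), annotOf(silent))
  igv <- cr[cr$region == "igv", ]
  expect_equal(igv$nVariableNt, 1L)
  expect_equal(igv$nSilent, 1L)
  expect_equal(igv$nReplacement, 0L)
  cr2 <- compareRegions(annotOf(refK), annotOf(repl))
  igv2 <- cr2[cr2$region == "igv", ]
  expect_equal(igv2$nVariableNt, 1L)
  expect_equal(igv2$nReplacement, 1L)
  expect_equal(igv2$nSilent, 0L)
  # all other regions silent
  expect_true(all(cr$nVariableNt[cr$region != "igv"] == 0L))
})

test_that("classifyCodonChange equals translate-and-compare over all
           61 x 61 sense-codon pairs", {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (a in sense) {
    aaA <- as.character(Biostrings::translate(Biostrings::DNAString(a),
      no.init.codon = TRUE))
    for (b in sense) {
      aaB <- as.character(Biostrings::translate(Biostrings::DNAString(b),
        no.init.codon = TRUE))
      want <- if (a == b) "none" else if (aaA == aaB) "silent" else "replacement"
      got <- classifyCodonChange(a, b)
      if (got != want)
        fail(sprintf("%s->%s: got %s want %s", a, b, got, want))
    }
  }
  succeed()
})

test_that("multi-hit codons count positions but classify once per codon
           under per-codon accounting", {
  g <- basePair(402)
  ref <- plantIgvCodon(g, 20, "AAA")           # Lys
  alt <- plantIgvCodon(ref, 20, "GAG")         # Glu, 2 nt changed
  crPos <- compareRegions(annotOf(ref), annotOf(alt), "per_position")
  crCod <- compareRegions(annotOf(ref), annotOf(alt), "per_codon")
  igvP <- crPos[crPos$region == "igv", ]
  igvC <- crCod[crCod$region == "igv", ]
  expect_equal(igvP$nVariableNt, 2L)
  expect_equal(igvP$nReplacement, 2L)          # one per changed position
  expect_equal(igvC$nVariableNt, 2L)
  expect_equal(igvC$nReplacement, 1L)          # one per changed codon
})

test_that("comparing a transcript with itself yields zero everywhere", {
  ann <- annotOf(basePair(403))
  cr <- compareRegions(ann, ann)
  expect_true(all(cr$nVariableNt == 0L))
  expect_true(all(cr$nSilent == 0L))
  expect_true(all(cr$nReplacement == 0L))
  expect_true(all(cr$nIndelNt == 0L))
})

test_that("reported positions agree with an independent translate-compare
           oracle on diverged genes", {
  f <- quickFamily(404, repeats = c(6L, 6L), stopHeptads = c(1L, 1L),
                   rates = c(utr5 = 0.03, signal = 0.03, igv = 0.03,
                             tm = 0.03, tail = 0.02, final_exon = 0.02))
  a1 <- annotateClone(spliceModel(f$genes[[1]]), f$genes[1], cloneId = "a")
  a2 <- annotateClone(spliceModel(f$genes[[2]]), f$genes[2], cloneId = "b")
  cr <- compareRegions(a1, a2)
  pos <- attr(cr, "positions")
  cod <- pos[!is.na(pos$class), ]
  expect_gt(nrow(cod), 5L)
  for (r in seq_len(nrow(cod))) {
    ci <- cod$codonIndex[r]; reg <- cod$region[r]
    rc <- bgalleles:::.codonsByRegion(a1)[[reg]]
    ac <- bgalleles:::.codonsByRegion(a2)[[reg]]
    aaR <- as.character(Biostrings::translate(
      Biostrings::DNAString(rc$codon[ci]), no.init.codon = TRUE))
    aaA <- as.character(Biostrings::translate(
      Biostrings::DNAString(ac$codon[ci]), no.init.codon = TRUE))
    expect_equal(cod$class[r],
                 if (aaR == aaA) "silent" else "replacement",
                 info = sprintf("%s codon %d", reg, ci))
  }
})

test_that("tails of unequal repeat count compare over shared units with
           indel blocks excluded", {
  cfg <- simulationConfig(seed = 405, repeatExonCounts = c(8L, 6L),
                          stopHeptads = c(1L, 1L), rates = zeroRates)
  fam <- simulateGeneFamily(cfg)
  a1 <- annotateClone(spliceModel(fam$genes[[1]]), fam$genes[1], cloneId = "a")
  a2 <- annotateClone(spliceModel(fam$genes[[2]]), fam$genes[2], cloneId = "b")
  cr <- compareRegions(a1, a2)
  tail <- cr[cr$region == "tail", ]
  expect_equal(tail$nIndelNt, 2L * 21L)
  expect_equal(tail$nVariableNt, 0L)
})

test_that("the selection summary applies the 2:1 neutral heuristic", {
  x <- data.frame(region = "igv", nSilent = 7, nReplacement = 12)
  s <- selectionSummary(x)
  expect_equal(s$ratio, 12 / 7, tolerance = 1e-9)
  expect_equal(s$flag, "not consistent with strong selection")
  s2 <- selectionSummary(data.frame(region = "tail", nSilent = 3,
                                    nReplacement = 14))
  expect_equal(s2$flag, "consistent with selection")
  s3 <- selectionSummary(data.frame(region = "tm", nSilent = 0,
                                    nReplacement = 0))
  expect_equal(s3$flag, "undefined (no silent changes)")
  expect_true(is.na(s3$ratio))
  # pooling over comparisons
  s4 <- selectionSummary(list(x, x))
  expect_equal(s4$nSilent, 14)
  expect_equal(s4$nReplacement, 24)
})

test_that("the variable-position census counts columns exactly", {
  expect_equal(variablePositionCensus(c("ACGT", "ACGT"))$nVariable, 0L)
  expect_equal(variablePositionCensus(c("ACGT", "ACGT"))$nTotal, 4L)
  cen <- variablePositionCensus(c("ACGT", "ACTT", "AC-A"))
  expect_equal(cen$nIndelColumns, 1L)
  expect_equal(cen$nTotal, 3L)
  expect_equal(cen$nVariable, 1L)  # column 4 varies; gap column 3 excluded
  cen2 <- variablePositionCensus(c("ACGT", "ACTT"))
  expect_equal(cen2$variablePositions, 3L)
  # masking removes columns from both counts
  cen3 <- variablePositionCensus(c("ACGT", "ACTT"), mask = 3L)
  expect_equal(cen3$nVariable, 0L)
  expect_equal(cen3$nTotal, 3L)
  expect_error(variablePositionCensus(character(0)), "non-empty")
  expect_error(variablePositionCensus(c("ACG", "AC")), "equal length")
})

test_that("the census recovers planted variable columns and ignores input
           order", {
  f <- quickFamily(406, repeats = c(5L, 5L, 5L), stopHeptads = 1L,
                   rates = c(igv = 0.02))
  ex2 <- vapply(f$genes, function(g) {
    ex <- modelExons(g)
    substr(as.character(genomicSeq(g)),
           IRanges::start(ex)[2], IRanges::end(ex)[2])
  }, character(1))
  cen <- variablePositionCensus(ex2)
  truthPos <- unique(unlist(lapply(f$famTruth$substitutions, function(s) {
    ex <- modelExons(f$genes[[1]])
    p <- s$genomicPos[s$region == "igv"]
    p - IRanges::start(ex)[2] + 1L
  })))
  # planted columns where genes actually differ
  mat <- do.call(rbind, strsplit(ex2, ""))
  realVar <- which(apply(mat, 2, function(x) length(unique(x)) > 1))
  expect_setequal(cen$variablePositions, realVar)
  expect_true(all(realVar %in% truthPos))
  cen2 <- variablePositionCensus(rev(ex2))
  expect_equal(cen$variablePositions, cen2$variablePositions)
})
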