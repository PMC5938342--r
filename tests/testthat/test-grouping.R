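test_that("zero-noise libraries group into exactly the simulated genes", {
  f <- quickFamily(201, repeats = c(7L, 6L, 5L, 4L, 8L),
                   stopHeptads = c(0L, 1L, 0L, 0L, 1L),
                   depth = 3L, retention = 0)
  anns <- annotateLibrary(f$lib, f$genes)
  groups <- groupByExon2(anns, cloneMeta(f$lib))
  expect_length(groups, 5L)
  # partition: every clone in exactly one group
  allIds <- sort(unname(unlist(lapply(groups, function(g) g@cloneIds))))
  expect_identical(allIds, sort(f$truth$clone_id))
  # membership matches the source genes
  for (g in groups) {
    src <- unique(f$truth$gene[f$truth$clone_id %in% g@cloneIds])
    expect_length(src, 1L)
    expect_identical(g@exon2Seq, bgalleles:::.exon2Of(anns[[g@cloneIds[1]]]))
  }
})

test_that("letters follow clone abundance and variants follow splice
           patterns", {
  f <- quickFamily(202, repeats = c(5L, 6L), depth = c(5L, 2L), retention = 0)
  anns <- annotateLibrary(f$lib, f$genes)
  groups <- groupByExon2(anns, cloneMeta(f$lib))
  expect_equal(vapply(groups, function(g) g@letter, character(1)), c("a", "b"))
  expect_equal(groupCloneCount(groups[[1]]), 5L)
  # clones differing only by a retained intron join one group as two variants
  cfg <- simulationConfig(seed = 203, repeatExonCounts = 5L,
                          rates = zeroRates)
  g1 <- simulateGeneFamily(cfg)$genes[[1]]
  spliced <- spliceModel(g1)
  withIntron <- bgalleles:::.spliceTranscript(g1, retained = 4L)$seq
  anns2 <- list(annotateClone(spliced, g1, cloneId = "c1"),
                annotateClone(withIntron, g1, cloneId = "c2"),
                annotateClone(spliced, g1, cloneId = "c3"))
  meta <- data.frame(clone_id = c("c1", "c2", "c3"), line = "N",
                     pcr_batch = c("PCR1", "PCR2", "PCR2"), n_observed = 1L)
  gr <- groupByExon2(anns2, meta)
  expect_length(gr, 1L)
  expect_equal(nrow(gr[[1]]@variants), 2L)
  expect_equal(gr[[1]]@variants$nClones, c(2L, 1L))
  nm <- nameSequences(gr)
  expect_equal(unname(nm[c("c1", "c3")]), c("NTBGa-1", "NTBGa-1"))
  expect_equal(unname(nm["c2"]), "NTBGa-2")
})

test_that("grouping and naming are stable under clone-order permutation", {
  f <- quickFamily(204, repeats = c(5L, 6L, 4L), depth = 2L, retention = 0.2)
  anns <- annotateLibrary(f$lib, f$genes)
  gr1 <- groupByExon2(anns, cloneMeta(f$lib))
  set.seed(1); perm <- sample(seq_along(anns))
  gr2 <- groupByExon2(anns[perm], cloneMeta(f$lib))
  expect_equal(lapply(gr1, function(g) g@cloneIds),
               lapply(gr2, function(g) g@cloneIds))
  expect_equal(nameSequences(gr1), nameSequences(gr2))
})

test_that("singleton flagging obeys all three conditions", {
  mk <- function(id, seq, line, batch) list(id = id, seq = seq,
                                            line = line, batch = batch)
  # dominant group: 3 clones of one exon2; singleton at hamming 1;
  # singleton at hamming 5; two-clone group at hamming 1
  base <- strrep("ACGT", 10)
  flip <- function(s, at, to) { substr(s, at, at) <- to; s }
  groupsFromSpec <- function(specs) {
    gs <- lapply(split(seq_along(specs), vapply(specs, `[[`, "", "seq")),
                 function(idx) {
      sp <- specs[idx]
      methods::new("GeneGroup", line = sp[[1]]$line,
        exon2Seq = sp[[1]]$seq, letter = "?",
        cloneIds = vapply(sp, `[[`, "", "id"),
        variants = data.frame(variant = 1L,
          representative = sp[[1]]$id,
          nClones = length(sp),
          nBatches = length(unique(vapply(sp, `[[`, "", "batch"))),
          cloneIdsCsv = paste(vapply(sp, `[[`, "", "id"), collapse = ",")),
        flags = if (length(unique(vapply(sp, `[[`, "", "batch"))) == 1L)
          "single_pcr_only" else character(0))
    })
    unname(gs)
  }
  specs <- c(
    lapply(1:3, function(i) mk(paste0("d", i), base, "N",
                               paste0("PCR", i %% 2 + 1))),
    list(mk("s1", flip(base, 5, "T"), "N", "PCR1")),
    list(mk("s5", flip(flip(flip(flip(flip(base, 1, "T"), 9, "A"),
                                13, "C"), 17, "G"), 21, "C"), "N", "PCR1")),
    list(mk("p1", flip(base, 30, "A"), "N", "PCR1"),
         mk("p2", flip(base, 30, "A"), "N", "PCR2")))
  gr <- flagSingletons(groupsFromSpec(specs))
  flagged <- vapply(gr, function(g)
    "possible_misincorporation" %in% g@flags, logical(1))
  ex2 <- vapply(gr, function(g) g@exon2Seq, character(1))
  expect_true(flagged[ex2 == flip(base, 5, "T")])       # 1-nt singleton
  expect_false(flagged[ex2 == base])                    # the dominant group
  expect_false(any(flagged[ex2 == flip(base, 30, "A")])) # 2-clone group
  expect_false(flagged[vapply(gr, function(g) "s5" %in% g@cloneIds,
                              logical(1))])             # 5-nt singleton
})

test_that("planted chimeras are called with the true breakpoint in the
           window, clean clones are not", {
  hits <- 0L; total <- 0L
  for (s in c(7, 11, 23, 41)) {
    f <- quickFamily(s, repeats = c(8L, 7L, 6L, 5L), depth = 2L,
                     retention = 0.15, chimeras = 1L)
    anns <- annotateLibrary(f$lib, f$genes)
    gr <- groupByExon2(anns, cloneMeta(f$lib))
    calls <- detectChimeras(anns, gr)
    chimId <- f$truth$clone_id[f$truth$is_chimera]
    expect_true(all(calls$clone_id %in% chimId),
                info = paste("false positives at seed", s))
    total <- total + 1L
    if (chimId %in% calls$clone_id) {
      hits <- hits + 1L
      bp <- f$truth$chimera_breakpoint[f$truth$is_chimera]
      row <- calls[calls$clone_id == chimId, ]
      expect_true(row$bp_start <= bp && bp <= row$bp_end,
                  info = paste("seed", s))
      expect_true(row$parent_a != row$parent_b)
    }
  }
  expect_gte(hits, total - 1L)
})

test_that("a clone with a single isolated substitution is not a chimera", {
  f <- quickFamily(303, repeats = c(8L, 7L), depth = 2L, retention = 0,
                   errors = 1L)
  anns <- annotateLibrary(f$lib, f$genes)
  gr <- groupByExon2(anns, cloneMeta(f$lib))
  calls <- detectChimeras(anns, gr)
  expect_equal(nrow(calls), 0L)
})

test_that("names follow the published convention", {
  v <- function(n) data.frame(variant = seq_len(n),
    representative = paste0("r", seq_len(n)), nClones = rev(seq_len(n)),
    nBatches = 1L, cloneIdsCsv = paste0("r", seq_len(n)))
  gA <- methods::new("GeneGroup", line = "N", exon2Seq = "AAA", letter = "a",
                     cloneIds = "r1", variants = v(1), flags = character(0))
  gB <- methods::new("GeneGroup", line = "15i", exon2Seq = "CCC",
                     letter = "b", cloneIds = c("r1", "r2", "r3"),
                     variants = v(3), flags = character(0))
  gD <- methods::new("GeneGroup", line = "6", exon2Seq = "GGG", letter = "d",
                     cloneIds = "r1", variants = v(1), flags = "letter_only")
  expect_equal(unname(nameSequences(list(gA))), "NTBGa-1")
  expect_equal(unname(nameSequences(list(gB))["r3"]), "15iTBGb-3")
  expect_equal(unname(nameSequences(list(gD))), "6TBGd")
  info <- parseCloneName(c("NTBGa-1", "15iTBGb-3", "6TBGd"))
  expect_equal(info$line, c("N", "15i", "6"))
  expect_equal(info$letter, c("a", "b", "d"))
  expect_equal(info$variant, c(1L, 3L, NA_integer_))
})

test_that("clones matching an exclusion list are dropped before grouping", {
  f <- quickFamily(205, repeats = c(5L, 6L), depth = 2L, retention = 0)
  anns <- annotateLibrary(f$lib, f$genes)
  ex2 <- bgalleles:::.exon2Of(anns[[1]])
  gr <- groupByExon2(anns, cloneMeta(f$lib), excludeExon2 = ex2)
  expect_length(gr, 1L)
  expect_false(any(vapply(gr, function(g) g@exon2Seq == ex2, logical(1))))
})
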