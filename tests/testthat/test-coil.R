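test_that("the register map is the fixed bijection onto a-g", {
  expect_equal(registerOfCodon(1), "e")
  expect_equal(registerOfCodon(3), "g")
  expect_equal(registerOfCodon(4), "a")
  expect_equal(registerOfCodon(7), "d")
  expect_setequal(registerOfCodon(1:7), letters[1:7])
  expect_equal(anyDuplicated(registerOfCodon(1:7)), 0L)
  # positions beyond 7 wrap into the next heptad
  expect_equal(registerOfCodon(8), "e")
})

test_that("residue chemistry follows the fixed partition", {
  expect_equal(classifyResidue("E"), "acidic")
  expect_equal(classifyResidue("C"), "cysteine")
  expect_equal(classifyResidue("L"), "hydrophobic")
  expect_equal(classifyResidue(c("K", "H")), c("basic", "basic"))
  expect_equal(classifyResidue("Y"), "polar")
  expect_equal(classifyResidue(c("G", "P")),
               rep("glycine_proline", 2))
  expect_error(classifyResidue("B"), "nonstandard")
})

test_that("register assignment depends only on codon-position provenance", {
  tab <- assignRegister(strrep("EKQLENL", 4))
  expect_equal(nrow(tab), 28L)
  expect_true(all(tapply(tab$register, tab$heptadIndex,
                         function(x) !anyDuplicated(x))))
  # a partial terminal heptad is allowed
  tab2 <- assignRegister(paste0(strrep("EKQLENL", 2), "EKQ"))
  expect_equal(max(tab2$heptadIndex), 3L)
  expect_equal(sum(tab2$heptadIndex == 3L), 3L)
  expect_error(assignRegister("EKQLENL", unitLengths = c(7L, 3L)),
               "provenance")
  # provenance from an annotated clone matches the exon structure
  gm <- canonicalGeneModel(nRepeats = 4L, stopHeptads = 1L)
  ann <- annotateClone(spliceModel(gm), gm)
  tab3 <- tailRegisterTable(ann)
  expect_equal(nrow(tab3), 35L)           # (4 + 1) x 7
  expect_equal(unique(table(tab3$heptadIndex)), 7L)
  expect_equal(sort(unique(tab3$sourceExon)), c(4L, 5L, 6L, 7L, 8L))
})

test_that("an ideal leucine zipper has hydrophobic a/d and nothing else", {
  # codon positions 4 and 7 are the a and d registers
  tab <- assignRegister(strrep("EKQLENL", 6))
  fr <- interfaceHydrophobicity(tab)
  expect_equal(unname(fr["a"]), 1)
  expect_equal(unname(fr["d"]), 1)
  expect_equal(unname(fr[c("b", "c", "e", "f", "g")]), rep(0, 5))
  # no hydrophobic residues at all
  fr0 <- interfaceHydrophobicity(assignRegister(strrep("EKQSENS", 4)))
  expect_true(all(fr0 == 0))
})

test_that("tails generated with an a/d hydrophobic bias show the published
           interface pattern", {
  set.seed(99)
  hydro <- c("L", "V", "I", "M", "A", "F")
  other <- c("E", "K", "Q", "S", "D", "R", "N", "T")
  mkUnit <- function() {
    u <- sample(other, 7, TRUE)
    u[4] <- sample(hydro, 1)                      # register a
    u[7] <- sample(hydro, 1)                      # register d
    if (runif(1) < 0.2) u[2] <- sample(hydro, 1)  # some noise elsewhere
    paste(u, collapse = "")
  }
  tab <- assignRegister(paste(replicate(30, mkUnit()), collapse = ""))
  fr <- interfaceHydrophobicity(tab)
  expect_true(all(fr["a"] > fr[c("b", "c", "e", "f", "g")]))
  expect_true(all(fr["d"] > fr[c("b", "c", "e", "f", "g")]))
})

test_that("variation decoration marks aligned differences by register", {
  t1 <- assignRegister(strrep("EKQLENL", 5))
  expect_equal(nrow(decorateVariation(list(a = t1, b = t1))$positions), 0L)
  # one substitution at codon position 4 -> one variable 'a' position
  s2 <- strsplit(strrep("EKQLENL", 5), "")[[1]]
  s2[3 * 7 + 4] <- "V"
  t2 <- assignRegister(paste(s2, collapse = ""))
  dv <- decorateVariation(list(a = t1, b = t2))
  expect_equal(nrow(dv$positions), 1L)
  expect_equal(dv$positions$register, "a")
  expect_equal(dv$positions$heptadIndex, 4L)
  expect_equal(unname(dv$countsByRegister["a"]), 1L)
  expect_true(dv$diAllelic)
  # counts are symmetric in input order
  dv2 <- decorateVariation(list(a = t2, b = t1))
  expect_equal(dv$countsByRegister, dv2$countsByRegister)
  # three states at one position -> not di-allelic
  s3 <- s2; s3[3 * 7 + 4] <- "T"
  t3 <- assignRegister(paste(s3, collapse = ""))
  dv3 <- decorateVariation(list(a = t1, b = t2, c = t3))
  expect_false(dv3$diAllelic)
})

test_that("whole-heptad insertions are reported separately, not as
           variable positions", {
  t1 <- assignRegister(strrep("EKQLENL", 6))
  ins <- paste0(strrep("EKQLENL", 3), strrep("GGGGGGG", 2),
                strrep("EKQLENL", 3))
  t2 <- assignRegister(ins)
  dv <- decorateVariation(list(ref = t1, longer = t2))
  expect_equal(dv$insertions$nInsertedHeptads, 2L)
  expect_equal(nrow(dv$positions), 0L)
})

test_that("patch calls equal brute-force window enumeration", {
  for (s in 1:10) {
    set.seed(s)
    tab <- randomRegisterTable(sample(10:25, 1))
    w <- sample(2:5, 1)
    th <- sample(c(0.4, 0.5, 0.6), 1)
    expect_equal(findPatches(tab, w, th), oraclePatches(tab, w, th),
                 info = paste("seed", s),
                 ignore_attr = "row.names")
  }
})

test_that("a C-terminal acidic stretch is called as a patch ending at the
           final heptad", {
  core <- strrep("EKQLENL", 8)
  acid <- strrep("DDALDED", 4)  # non-interface positions all D/E
  tab <- assignRegister(paste0(core, acid))
  calls <- findPatches(tab)
  acidCalls <- calls[calls$chemClass == "acidic", ]
  expect_gte(nrow(acidCalls), 1L)
  expect_equal(max(acidCalls$endHeptad), 12L)
})

test_that("uniform random tails rarely qualify at threshold 0.8; threshold
           0 degenerates to one whole-tail call per present class", {
  nCalls <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    nrow(findPatches(randomRegisterTable(20L), threshold = 0.8))
  }, numeric(1))
  expect_gte(sum(nCalls == 0L), 15L)
  tab <- assignRegister(strrep("DKQLSNL", 10))  # acidic e, basic f, polar c/g
  calls0 <- findPatches(tab, threshold = 0)
  expect_setequal(calls0$chemClass, c("acidic", "basic", "polar"))
  expect_true(all(calls0$startHeptad == 1L & calls0$endHeptad == 10L))
})

test_that("the text wheel renders one line per repeat unit", {
  tab <- assignRegister(strrep("EKQLENL", 3))
  lines <- wheelText(tab)
  expect_length(lines, 4L)  # header + 3 units
  expect_match(lines[1], "4\\(a\\)")
})
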