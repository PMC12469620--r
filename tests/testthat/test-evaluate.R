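mkHits <- function(chroms, scores) {
  gr <- GenomicRanges::GRanges(chroms,
                               IRanges::IRanges(seq_along(chroms) * 1000L,
                                                width = 200L))
  S4Vectors::mcols(gr)$score <- as.integer(scores)
  gr
}

test_that("decoy filtering removes non-primary contigs by name pattern", {
  hits <- mkHits(c("chr1", "chrUn_KI270302v1", "chr3_alt", "chr2"),
                 c(1000, 1000, 900, 800))
  kept <- filterDecoys(hits)
  # independent name-filter oracle
  nm <- c("chr1", "chrUn_KI270302v1", "chr3_alt", "chr2")
  oracleKeep <- !grepl("chrUn|_alt|_random|_decoy|_fix|HLA-", nm)
  expect_identical(as.character(GenomicRanges::seqnames(kept)),
                   nm[oracleKeep])
  # empty pattern list is the identity
  expect_identical(length(filterDecoys(hits, character(0))), length(hits))
  # everything on decoys -> empty
  all_decoy <- mkHits(c("chrUn_1", "chr9_alt"), c(1000, 1000))
  expect_identical(length(filterDecoys(all_decoy)), 0L)
})

test_that("score filtering uses a strict less-than-750 cut", {
  hits <- mkHits(rep("chr1", 4), c(1000, 800, 750, 749))
  kept <- filterLowScore(hits)
  expect_identical(kept$score, c(1000L, 800L, 750L))
  expect_identical(length(filterLowScore(mkHits("chr1", 1000))), 1L)

  # one-line threshold oracle over random score lists
  set.seed(61)
  for (i in 1:10) {
    scores <- sample(0:1000, 20, replace = TRUE)
    kept <- filterLowScore(mkHits(rep("chr1", 20), scores))
    expect_identical(kept$score, as.integer(scores[scores >= 750]))
  }
})

test_that("decoy and score filters commute", {
  set.seed(62)
  chroms <- sample(c("chr1", "chr2", "chrUn_x", "chr5_random"), 30, TRUE)
  scores <- sample(600:1000, 30, TRUE)
  hits <- mkHits(chroms, scores)
  a <- filterLowScore(filterDecoys(hits))
  b <- filterDecoys(filterLowScore(hits))
  expect_identical(as.character(GenomicRanges::seqnames(a)),
                   as.character(GenomicRanges::seqnames(b)))
  expect_identical(a$score, b$score)
})

test_that("mismatch localization recovers planted edits and matches bindings", {
  fix <- makeSimpleFixture(seed = 71)
  pair <- designOnFixture(fix)
  hits <- scanPrimerPair(pair, fix$genome)
  mm <- locateMismatches(hits[1], pair)
  expect_identical(mm$fwd$n, 0L)
  expect_identical(mm$rev$n, 0L)

  # plant a duplicate with a single substitution at fwd-primer offset 7
  dup <- plantOffTarget(fix$genome, "chr1", pair@ampliconStart + 1L,
                        pair@ampliconEnd, "chr1", 3000L, divergence = 0)
  g <- substituteBases(dup$genome, "chr1", dup$destStart + 7L, seed = 5)
  hits2 <- scanPrimerPair(pair, g)
  off <- hits2[!hits2$isOnTarget & hits2$pairing == "FR"]
  expect_identical(length(off), 1L)
  mm2 <- locateMismatches(off, pair)
  expect_identical(mm2$fwd$n, 1L)
  expect_identical(mm2$fwd$positions, 7L)
  expect_identical(mm2$rev$n, 0L)
  # agrees with the binding's stored record
  expect_identical(off$nMismLeft, 1L)
  expect_identical(off$mismLeft, "7")

  # strand-flip fixture: mismatch positions are invariant to the hosting
  # strand of the planted copy
  src <- as.character(subseq(fix$genome[["chr1"]], pair@ampliconStart + 1L,
                             pair@ampliconEnd))
  srcMut <- mutateSeq(src, 8)   # fwd-primer offset 7
  gFlip <- fix$genome
  gFlip[["chr1"]] <- replaceAt(gFlip[["chr1"]],
                               IRanges::IRanges(3000, 2999 + nchar(srcMut)),
                               DNAStringSet(rcChar(srcMut))[[1]])
  hits3 <- scanPrimerPair(pair, gFlip)
  off3 <- hits3[!hits3$isOnTarget & hits3$pairing == "FR"]
  expect_identical(length(off3), 1L)
  mm3 <- locateMismatches(off3, pair)
  expect_identical(mm3$fwd$positions, 7L)
  expect_identical(mm3$rev$n, 0L)
})

test_that("normalized match equals the LCS dynamic program", {
  # identity
  x <- "ACGTACGTACGTACGTACGT"
  nm <- normalizedMatch(x, x)
  expect_equal(unname(nm), c(1, 1))

  # exact prefix of half length
  gold <- randomDna(20)
  off <- substr(gold, 1, 10)
  nm <- normalizedMatch(off, gold)
  expect_equal(unname(nm["toTest"]), 1.0)
  expect_equal(unname(nm["toGold"]), 0.5)

  # brute-force oracle on 4-mers
  expect_equal(unname(normalizedMatch("ACGT", "TGCA")["toTest"]),
               lcsLength("ACGT", "TGCA") / 4)
  set.seed(72)
  for (i in 1:30) {
    a <- randomDna(4); b <- randomDna(4)
    expect_equal(unname(normalizedMatch(a, b)["toTest"]),
                 lcsLength(a, b) / 4)
  }
  # and on random 30-mer pairs
  for (i in 1:10) {
    a <- randomDna(30); b <- randomDna(30)
    expect_equal(unname(normalizedMatch(a, b)["toTest"]),
                 lcsLength(a, b) / 30)
  }
  expect_error(normalizedMatch("", "ACGT"), "non-empty")
})

test_that("classification is boundary-inclusive at 80% and monotone", {
  expect_identical(classifyOffTarget(1.0, 1.0), "HQ")
  expect_identical(classifyOffTarget(0.799, 0.5), "LQ")
  expect_identical(classifyOffTarget(0.80, 0.5), "HQ")
  expect_identical(classifyOffTarget(0.5, 0.80), "HQ")

  set.seed(73)
  for (i in 1:20) {
    tt <- runif(1); tg <- runif(1)
    k1 <- classifyOffTarget(tt, tg)
    k2 <- classifyOffTarget(min(tt + runif(1, 0, 0.2), 1), tg)
    if (k1 == "HQ") expect_identical(k2, "HQ")
  }
  # self-alignment is always HQ
  for (i in 1:5) {
    s <- randomDna(sample(5:50, 1))
    nm <- normalizedMatch(s, s)
    expect_identical(unname(classifyOffTarget(nm["toTest"], nm["toGold"])),
                     "HQ")
  }
})

test_that("site assessment counts off-targets and flags concerning sites", {
  fix <- makeSimpleFixture(seed = 74)
  pair <- designOnFixture(fix)

  # clean site: primer count 1, not concerning
  hits <- scanPrimerPair(pair, fix$genome)
  a0 <- assessSite(pair, hits, fix$genome)
  expect_true(a0@ispcrOk)
  expect_identical(primerCount(a0), 1L)
  expect_false(isConcerning(a0))

  # one exact duplicate: primer count 2, concerning (nm = 1.0 -> HQ)
  dup <- plantOffTarget(fix$genome, "chr1", pair@ampliconStart + 1L,
                        pair@ampliconEnd, "chr1", 5000L, divergence = 0)
  a1 <- assessSite(pair, scanPrimerPair(pair, dup$genome), dup$genome)
  expect_identical(primerCount(a1), 2L)
  expect_true(isConcerning(a1))
  expect_identical(offTargets(a1)$class, "HQ")
  expect_equal(offTargets(a1)$nmToTest, 1.0)

  # two heavily diverged duplicates with intact primer footprints:
  # primer count 3, but similarity below 80% -> not concerning
  fwdLen <- nchar(pair@fwdSeq); revLen <- nchar(pair@revSeq)
  d1 <- plantOffTarget(fix$genome, "chr1", pair@ampliconStart + 1L,
                       pair@ampliconEnd, "chr1", 5000L, divergence = 0.40,
                       preservePrimerSites = TRUE, fwdLen = fwdLen,
                       revLen = revLen, seed = 81)
  d2 <- plantOffTarget(d1$genome, "chr1", pair@ampliconStart + 1L,
                       pair@ampliconEnd, "chr1", 10000L, divergence = 0.40,
                       preservePrimerSites = TRUE, fwdLen = fwdLen,
                       revLen = revLen, seed = 82)
  a2 <- assessSite(pair, scanPrimerPair(pair, d2$genome), d2$genome)
  expect_identical(primerCount(a2), 3L)
  # verify the classification against the oracle-computed similarity
  gold <- as.character(subseq(fix$genome[["chr1"]], pair@ampliconStart + 1L,
                              pair@ampliconEnd))
  for (k in seq_len(nrow(offTargets(a2)))) {
    od <- offTargets(a2)[k, ]
    offSeq <- as.character(subseq(d2$genome[["chr1"]], od$start + 1L,
                                  od$end))
    oracleNm <- lcsLength(offSeq, gold) / nchar(offSeq)
    expect_equal(od$nmToTest, oracleNm)
    expect_identical(od$class, if (max(od$nmToTest, od$nmToGold) >= 0.8)
      "HQ" else "LQ")
  }
  expect_false(isConcerning(a2))

  # mutating a primer footprint at the 3' terminus removes the off-target
  g3 <- substituteBases(dup$genome, "chr1",
                        dup$destStart + fwdLen - 1L, seed = 9)
  a3 <- assessSite(pair, scanPrimerPair(pair, g3), g3)
  offFR <- offTargets(a3)[offTargets(a3)$pairing == "FR", ]
  expect_identical(nrow(offFR), 0L)
})

test_that("assessment without an on-target hit falls back to the predicted amplicon", {
  fix <- makeSimpleFixture(seed = 75)
  pair <- designOnFixture(fix)
  hits <- scanPrimerPair(pair, fix$genome)
  noOn <- hits[!hits$isOnTarget]   # drop everything
  a <- assessSite(pair, noOn, fix$genome)
  expect_false(a@ispcrOk)
  expect_identical(primerCount(a), 1L)
})
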