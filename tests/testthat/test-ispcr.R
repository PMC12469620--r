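fakePair <- function(fwd, rev, chrom = "chr1", targetPos = 500L,
                     ampStart = 400L, ampEnd = 600L) {
  new("PrimerPair", pairName = "p_c_1_TAS-opt", fwdName = "p_c_1_TAS-opt_F",
      revName = "p_c_1_TAS-opt_R", fwdSeq = fwd, revSeq = rev,
      fwdTm = 60, revTm = 60, mode = "TAS_OPT", chrom = chrom,
      targetPos = targetPos, predictedProduct = ampEnd - ampStart,
      ampliconStart = ampStart, ampliconEnd = ampEnd)
}

test_that("query pairings enumerate FR, FF, and RR exactly once", {
  pair <- fakePair("ACGTACGTACGTACGTACGT", "TTGCAAGCTTGCAAGCTTGC")
  qp <- buildQueryPairings(pair)
  expect_identical(qp$pairing, c("FR", "FF", "RR"))
  expect_identical(qp$left, c(pair@fwdSeq, pair@fwdSeq, pair@revSeq))
  expect_identical(qp$right, c(pair@revSeq, pair@fwdSeq, pair@revSeq))

  same <- fakePair("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT")
  qps <- buildQueryPairings(same)
  expect_identical(nrow(qps), 3L)
  expect_true(all(qps$left == qps$right))
})

test_that("a verbatim planted primer yields exactly one plus-strand binding", {
  set.seed(21)
  genome <- simulateGenome(c(chr1 = 50000L), seed = 21)
  primer <- randomDna(20)
  genome[["chr1"]] <- replaceAt(genome[["chr1"]],
                                IRanges::IRanges(30000, 30019),
                                DNAStringSet(primer)[[1]])
  b <- findBindings(primer, genome)
  oracle <- bruteForceBindings(primer, genome, MatcherParams())
  expect_identical(bindingKey(b), bindingKey(oracle))
  expect_identical(nrow(b), 1L)
  expect_identical(b$strand, "+")
  expect_identical(b$start, 30000L)
  expect_identical(b$nMismatch, 0L)
})

test_that("a 3'-terminal mismatch disqualifies a binding (minPerfect rule)", {
  set.seed(22)
  genome <- simulateGenome(c(chr1 = 20000L), seed = 22)
  primer <- randomDna(20)
  copy <- mutateSeq(primer, 20)   # mismatch at the 3'-terminal base
  genome[["chr1"]] <- replaceAt(genome[["chr1"]],
                                IRanges::IRanges(10000, 10019),
                                DNAStringSet(copy)[[1]])
  b <- findBindings(primer, genome)
  expect_identical(nrow(b), 0L)
  expect_identical(nrow(bruteForceBindings(primer, genome, MatcherParams())),
                   0L)
})

test_that("the minGood two-matches-per-mismatch rule decides edge cases", {
  set.seed(23)
  genome <- simulateGenome(c(chr1 = 20000L), seed = 23)
  primer <- randomDna(20)
  # 3 mismatches inside the 3'-most 15 bases, none in the last 5 (so the
  # seed 11-mer at offset 0 stays intact): 12 matches >= 2*3 -> accepted
  copy3 <- mutateSeq(primer, c(12, 13, 14))
  genome[["chr1"]] <- replaceAt(genome[["chr1"]],
                                IRanges::IRanges(5000, 5019),
                                DNAStringSet(copy3)[[1]])
  b3 <- findBindings(primer, genome)
  expect_identical(bindingKey(b3),
                   bindingKey(bruteForceBindings(primer, genome,
                                                 MatcherParams())))
  expect_true(any(b3$start == 5000L & b3$nMismatch == 3L))

  # 6 mismatches in the window can never satisfy 9 >= 12
  genome2 <- simulateGenome(c(chr1 = 20000L), seed = 23)
  copy6 <- mutateSeq(primer, c(6, 7, 12, 13, 14, 15))
  genome2[["chr1"]] <- replaceAt(genome2[["chr1"]],
                                 IRanges::IRanges(5000, 5019),
                                 DNAStringSet(copy6)[[1]])
  b6 <- findBindings(primer, genome2)
  expect_false(any(b6$start == 5000L))
})

test_that("primers shorter than the tile size are rejected", {
  genome <- simulateGenome(c(chr1 = 1000L), seed = 1)
  expect_error(findBindings("ACGTACGT", genome), "tileSize")
})

test_that("binding pairing follows coordinate arithmetic and orientation", {
  params <- MatcherParams()
  mkb <- function(strand, start, len = 20L)
    data.frame(chrom = "chr1", strand = strand, start = as.integer(start),
               end = as.integer(start) + len - 1L, nMismatch = 0L,
               mismatches = I(list(integer(0))))
  # convergent, outer span 190
  hits <- pairBindings(mkb("+", 1000), mkb("-", 1170), params)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$end - hits$start + 1L, 190L)

  # outer span 801 exceeds maxSize 800 -> no product
  expect_identical(nrow(pairBindings(mkb("+", 1000), mkb("-", 1781),
                                     params)), 0L)
  # span exactly 800 is allowed
  expect_identical(nrow(pairBindings(mkb("+", 1000), mkb("-", 1780),
                                     params)), 1L)
  # divergent (minus binding upstream of plus binding) -> no product
  expect_identical(nrow(pairBindings(mkb("+", 1000), mkb("-", 500),
                                     params)), 0L)
  # different contigs never pair
  right <- mkb("-", 1170); right$chrom <- "chr2"
  expect_identical(nrow(pairBindings(mkb("+", 1000), right, params)), 0L)
})

test_that("hit scores honor the documented penalty scheme", {
  # perfect hits score exactly 1000
  expect_identical(ispcrScore(integer(0), integer(0), 20, 20), 1000L)

  # exhaustive oracle over all single-mismatch positions of a 20-mer:
  # weight 2/L in the 3'-most 5 bases, else 1/L, halved across primers
  for (posn in 0:19) {
    w <- ifelse(posn >= 15, 2, 1) / 20
    expected <- as.integer(round(1000 * (1 - w / 2)))
    expect_identical(ispcrScore(posn, integer(0), 20, 20), expected)
  }

  # adding a mismatch never increases the score
  set.seed(31)
  for (i in 1:20) {
    len <- sample(18:25, 1)
    base <- sort(sample(0:(len - 1), sample(0:3, 1)))
    extra <- sample(setdiff(0:(len - 1), base), 1)
    expect_lte(ispcrScore(list(sort(c(base, extra))), list(integer(0)),
                          len, len),
               ispcrScore(list(base), list(integer(0)), len, len))
  }

  # 3'-proximal mismatches are penalized at least as heavily
  expect_lte(ispcrScore(19, integer(0), 20, 20),
             ispcrScore(2, integer(0), 20, 20))
})

test_that("scan of a designed pair finds a single perfect on-target hit", {
  fix <- makeSimpleFixture(seed = 41)
  pair <- designOnFixture(fix)
  hits <- scanPrimerPair(pair, fix$genome)
  expect_identical(length(hits), 1L)
  expect_true(hits$isOnTarget)
  expect_identical(hits$score, 1000L)
  expect_identical(hits$pairing, "FR")
  # product sequence equals the reference slice
  expect_identical(hits$productSeq,
                   as.character(subseq(fix$genome[["chr1"]],
                                       GenomicRanges::start(hits),
                                       GenomicRanges::end(hits))))
})

test_that("an exact duplicate amplicon yields one on- and one off-target", {
  fix <- makeSimpleFixture(seed = 42)
  pair <- designOnFixture(fix)
  planted <- plantOffTarget(fix$genome, "chr1",
                            pair@ampliconStart + 1L, pair@ampliconEnd,
                            "chr1", 5000L, divergence = 0)
  hits <- scanPrimerPair(pair, planted$genome)
  expect_identical(length(hits), 2L)
  expect_identical(sum(hits$isOnTarget), 1L)
  expect_identical(hits$score, c(1000L, 1000L))
  on <- hits[hits$isOnTarget]
  expect_identical(GenomicRanges::start(on) - 1L, pair@ampliconStart)
})

test_that("hits are invariant to splitting the genome between products", {
  fix <- makeSimpleFixture(seed = 43, len = 40000L, pos = 30000L)
  pair <- designOnFixture(fix)
  planted <- plantOffTarget(fix$genome, "chr1",
                            pair@ampliconStart + 1L, pair@ampliconEnd,
                            "chr1", 5000L, divergence = 0)
  whole <- scanPrimerPair(pair, planted$genome)

  # split at 15000, outside both products
  seqStr <- as.character(planted$genome[["chr1"]])
  splitG <- DNAStringSet(c(chr1 = substr(seqStr, 1, 15000),
                           chr1b = substr(seqStr, 15001, nchar(seqStr))))
  pair2 <- pair
  pair2@chrom <- "chr1b"
  pair2@targetPos <- pair@targetPos - 15000L
  pair2@ampliconStart <- pair@ampliconStart - 15000L
  pair2@ampliconEnd <- pair@ampliconEnd - 15000L
  split <- scanPrimerPair(pair2, splitG)
  expect_identical(length(split), length(whole))
  offW <- whole[!whole$isOnTarget]
  offS <- split[!split$isOnTarget]
  expect_identical(GenomicRanges::start(offS), GenomicRanges::start(offW))
  onS <- split[split$isOnTarget]
  expect_identical(GenomicRanges::start(onS) + 15000L,
                   GenomicRanges::start(whole[whole$isOnTarget]))
})

test_that("internal matcher equals the brute-force matcher on random fixtures", {
  set.seed(51)
  params <- MatcherParams()
  for (rep in 1:12) {
    len <- sample(10000:40000, 1)
    genome <- simulateGenome(c(chr1 = len), seed = 1000 + rep)
    primer <- randomDna(sample(18:25, 1))
    nMut <- sample(0:4, 1)
    copy <- if (nMut > 0)
      mutateSeq(primer, sample(nchar(primer), nMut)) else primer
    at <- sample(len - 100, 1)
    strandFlip <- runif(1) < 0.5
    ins <- if (strandFlip) rcChar(copy) else copy
    genome[["chr1"]] <- replaceAt(genome[["chr1"]],
                                  IRanges::IRanges(at, at + nchar(ins) - 1L),
                                  DNAStringSet(ins)[[1]])
    b <- findBindings(primer, genome, params)
    oracle <- bruteForceBindings(primer, genome, params)
    expect_identical(bindingKey(b), bindingKey(oracle))
  }
})

test_that("hit exports round-trip coordinates in BED and FASTA headers", {
  fix <- makeSimpleFixture(seed = 44)
  pair <- designOnFixture(fix)
  hits <- scanPrimerPair(pair, fix$genome)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeHitsBed(hits, bed)
  tab <- read.table(bed, sep = "\t")
  expect_identical(tab$V2, GenomicRanges::start(hits) - 1L)
  expect_identical(tab$V3, GenomicRanges::end(hits))
  expect_identical(tab$V5, hits$score)

  fa <- withr::local_tempfile(fileext = ".fa")
  writeProductsFasta(hits, fa)
  seqs <- readDNAStringSet(fa)
  expect_identical(as.character(seqs[[1]]), hits$productSeq[1])
  expect_match(names(seqs)[1], "pairing=FR")
  expect_match(names(seqs)[1],
               sprintf("chr1:%d-%d", GenomicRanges::start(hits) - 1L,
                       GenomicRanges::end(hits)))
})
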