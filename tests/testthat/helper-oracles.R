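# Independent oracles used by derived-value and property tests. These are
# deliberately separate implementations (vectorized exhaustive scans and
# textbook formulas), not calls into the code paths they check.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

DNA <- c("A", "C", "G", "T")

randomDna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

mutateSeq <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) ch[p] <- sample(setdiff(DNA, ch[p]), 1)
  paste(ch, collapse = "")
}

rcChar <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Exhaustive all-offsets, both-strands matcher applying the same acceptance
# rules as the engine (exact 3'-terminal minPerfect; >= 2 matches per
# mismatch in the 3'-most minGood window; at least one exact tile at the
# locus), evaluated by dense logical matrices rather than seeding.
bruteForceBindings <- function(primer, genome, params) {
  L <- nchar(primer)
  tile <- params@tileSize
  tileOffsets <- seq(0L, L - tile, by = params@stepSize)
  wlen <- min(params@minGood, L)
  out <- list()
  for (chrom in names(genome)) {
    contigChars <- strsplit(as.character(genome[[chrom]]), "")[[1]]
    n <- length(contigChars)
    if (n < L) next
    S <- n - L + 1L
    for (str in c("+", "-")) {
      query <- if (str == "+") primer else rcChar(primer)
      qChars <- strsplit(query, "")[[1]]
      M <- vapply(seq_len(L), function(j)
        contigChars[j:(j + S - 1L)] == qChars[j], logical(S))
      # map query column j (1..L) to primer 5' offset
      offsetOf <- function(j) if (str == "+") j - 1L else L - j
      colsFor <- function(offsets) {
        j <- if (str == "+") offsets + 1L else L - offsets
        sort(j)
      }
      termCols <- colsFor((L - params@minPerfect):(L - 1L))
      winCols <- colsFor((L - wlen):(L - 1L))
      ok1 <- rowSums(!M[, termCols, drop = FALSE]) == 0L
      mmW <- rowSums(!M[, winCols, drop = FALSE])
      ok2 <- (wlen - mmW) >= 2L * mmW
      seedOk <- rep(FALSE, S)
      for (o in tileOffsets) {
        cols <- colsFor(o:(o + tile - 1L))
        seedOk <- seedOk | rowSums(M[, cols, drop = FALSE]) == tile
      }
      hits <- which(ok1 & ok2 & seedOk)
      for (s in hits) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, strand = str, start = s, end = s + L - 1L,
          nMismatch = sum(!M[s, ]))
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      nMismatch = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$strand, res$start), , drop = FALSE]
}

bindingKey <- function(df)
  sort(paste(df$chrom, df$strand, df$start, df$end, df$nMismatch))

# Classic LCS dynamic program: the maximum number of matched pairs in any
# monotone gapless-cost alignment (match +1, mismatch 0, gaps 0).
lcsLength <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  prev <- integer(length(B) + 1L)
  for (i in seq_along(A)) {
    cur <- integer(length(B) + 1L)
    for (j in seq_along(B)) {
      cur[j + 1L] <- max(prev[j] + (A[i] == B[j]), prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[length(B) + 1L]
}

# Wilson interval via the quadratic-root form: the two roots of
# (p - phat)^2 = z^2 p (1 - p) / n.
wilsonRoots <- function(alt, n, confidence = 0.95) {
  z <- qnorm(1 - (1 - confidence) / 2)
  phat <- alt / n
  disc <- z * sqrt(z^2 + 4 * n * phat * (1 - phat))
  lower <- (2 * n * phat + z^2 - disc) / (2 * (n + z^2))
  upper <- (2 * n * phat + z^2 + disc) / (2 * (n + z^2))
  c(lower = lower, upper = upper)
}

# A designable uniform-random fixture: genome plus one centered target.
makeSimpleFixture <- function(seed = 1, len = 50000L, pos = NULL,
                              chrom = "chr1", proj = "sim") {
  genome <- simulateGenome(stats::setNames(len, chrom), seed = seed)
  if (is.null(pos)) pos <- as.integer(len / 2)
  list(genome = genome,
       targets = data.frame(CHROM = chrom, POS = pos, PROJ = proj))
}

# Design one pair on a simple fixture (first mode that succeeds).
designOnFixture <- function(fix, flank = 500L) {
  out <- waterfallDesign(fix$targets, fix$genome, flank = flank)[[1]]
  stopifnot(out@primer3Ok)
  out@pair
}
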