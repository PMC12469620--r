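#' Default decoy-contig name patterns
#'
#' Off-target hits on non-primary reference contigs (alternate haplotypes,
#' unplaced/random scaffolds, decoy and fix-patch sequence, HLA contigs)
#' are removed before evaluation. A contig is a decoy when its name
#' contains any of these substrings; the list is configurable wherever it
#' is consumed.
#'
#' @return character vector of name substrings
#' @export
#' @examples
#' decoyPatterns()
decoyPatterns <- function() {
  c("_alt", "_random", "_decoy", "chrUn", "_fix", "HLA-")
}

#' Remove hits on decoy contigs
#'
#' @param hits a hit `GRanges` from [scanPrimerPair()]
#' @param patterns contig-name substrings identifying decoys; an empty
#'   vector disables filtering
#' @return the filtered `GRanges`, order preserved
#' @export
filterDecoys <- function(hits, patterns = decoyPatterns()) {
  if (length(hits) == 0L || length(patterns) == 0L) return(hits)
  nm <- as.character(GenomicRanges::seqnames(hits))
  isDecoy <- Reduce(`|`, lapply(patterns, function(p)
    grepl(p, nm, fixed = TRUE)))
  hits[!isDecoy]
}

#' Remove low-scoring hits
#'
#' Drops hits whose in-silico PCR score falls strictly below the
#' threshold; a hit scoring exactly the threshold is retained. The default
#' of 750 removes extremely low-quality off-targets before alignment-based
#' evaluation.
#'
#' @param hits a hit `GRanges` from [scanPrimerPair()]
#' @param minScore retention threshold on the 0-1000 score scale
#' @return the filtered `GRanges`, order preserved
#' @export
filterLowScore <- function(hits, minScore = 750L) {
  if (length(hits) == 0L) return(hits)
  hits[hits$score >= minScore]
}

#' Locate per-primer mismatches within a hit's product sequence
#'
#' Re-derives each primer's mismatches directly from the product sequence:
#' the left-binding primer is compared against the product's 5' terminus
#' and the right-binding primer against the reverse complement of its 3'
#' terminus. Offsets are 0-based from each primer's 5' end. Results are
#' reported per design primer (forward/reverse) using the hit's recorded
#' binding roles, so they are invariant to which contig strand hosted the
#' product.
#'
#' @param hit a length-1 hit `GRanges` from [scanPrimerPair()]
#' @param pair the [PrimerPair-class] that produced the hit
#' @return list with elements `fwd` and `rev`, each `list(n, positions)`
#' @export
locateMismatches <- function(hit, pair) {
  stopifnot(length(hit) == 1L, is(pair, "PrimerPair"))
  product <- hit$productSeq
  lenL <- hit$leftEnd - hit$leftStart + 1L
  lenR <- hit$rightEnd - hit$rightStart + 1L
  if (nchar(product) < lenL || nchar(product) < lenR)
    stop("malformed hit: product shorter than a primer")
  leftPrimer <- if (hit$leftRole == "F") pair@fwdSeq else pair@revSeq
  rightPrimer <- if (hit$rightRole == "F") pair@fwdSeq else pair@revSeq

  cmp <- function(primer, segment) {
    a <- strsplit(primer, "")[[1]]
    b <- strsplit(segment, "")[[1]]
    sort(which(a != b) - 1L)
  }
  leftMism <- cmp(leftPrimer, substr(product, 1L, lenL))
  rightMism <- cmp(rightPrimer,
                   revComp(substr(product, nchar(product) - lenR + 1L,
                                  nchar(product))))
  res <- list()
  res[[if (hit$leftRole == "F") "fwd" else "rev"]] <-
    list(n = length(leftMism), positions = leftMism)
  res[[if (hit$rightRole == "F") "fwd" else "rev"]] <-
    list(n = length(rightMism), positions = rightMism)
  res[c("fwd", "rev")]
}

#' Normalized alignment similarity between two amplicons
#'
#' Globally aligns the off-target amplicon to the on-target ("gold")
#' amplicon with match = +1, mismatch = 0, and no gap costs, so the score
#' equals the size of the best co-linear match set. The score is
#' normalized twice: by the off-target length (`toTest`) and by the
#' on-target length (`toGold`), so off-target amplicons of any size are
#' measured properly.
#'
#' @param off off-target amplicon sequence (non-empty)
#' @param gold on-target amplicon sequence (non-empty)
#' @return named numeric vector `c(toTest = , toGold = )`
#' @export
#' @examples
#' normalizedMatch("ACGTACGTAC", "ACGTACGTAC")  # identical: both 1.0
normalizedMatch <- function(off, gold) {
  if (!nzchar(off) || !nzchar(gold))
    stop("amplicon sequences must be non-empty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0)
  score <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(off), Biostrings::DNAString(gold),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 0, scoreOnly = TRUE)
  c(toTest = score / nchar(off), toGold = score / nchar(gold))
}

#' Classify an off-target as high or low quality
#'
#' An off-target whose normalized match reaches the threshold (80% by
#' default, boundary inclusive) is a high-quality, concerning off-target
#' (HQ); below it, low-quality (LQ). The driving statistic is the larger
#' of the two normalized values (the conservative, more-flagging choice);
#' both values are retained in all detail tables so users can re-threshold.
#'
#' @param toTest,toGold normalized match values (vectors recycle)
#' @param threshold HQ boundary on the normalized-match scale
#' @return character vector of "HQ"/"LQ"
#' @export
#' @examples
#' classifyOffTarget(0.799, 0.5)  # LQ
#' classifyOffTarget(0.80, 0.5)   # HQ (boundary inclusive)
classifyOffTarget <- function(toTest, toGold, threshold = 0.80) {
  ifelse(pmax(toTest, toGold) >= threshold, "HQ", "LQ")
}

#' Assess one site from its filtered hit list
#'
#' Identifies the on-target hit (flagged during the scan), aligns every
#' remaining hit's product to the on-target amplicon, classifies each as
#' HQ/LQ, and summarizes: `primerCount` is 1 plus the number of retained
#' off-targets, and `concerning` is TRUE when any off-target is HQ. When
#' the on-target hit is absent (everything was filtered), off-targets are
#' still evaluated against the design-predicted amplicon slice of the
#' reference, and `ispcrOk` is FALSE.
#'
#' @param pair the [PrimerPair-class] for the site
#' @param hits decoy- and score-filtered hit `GRanges`
#' @param genome reference genome (used for the predicted amplicon when
#'   the on-target hit is absent)
#' @param hqThreshold HQ classification boundary
#' @return a [SiteAssessment-class]
#' @export
assessSite <- function(pair, hits, genome, hqThreshold = 0.80) {
  stopifnot(is(pair, "PrimerPair"))
  onIdx <- which(hits$isOnTarget)
  ispcrOk <- length(onIdx) > 0L
  gold <- if (ispcrOk) {
    hits$productSeq[onIdx[1]]
  } else {
    genome <- asGenome(genome)
    as.character(Biostrings::subseq(genome[[pair@chrom]],
                                    pair@ampliconStart + 1L,
                                    pair@ampliconEnd))
  }
  off <- if (length(hits)) hits[!hits$isOnTarget] else hits
  if (length(off) > 0L) {
    nm <- t(vapply(off$productSeq, normalizedMatch, gold = gold,
                   c(toTest = 0.0, toGold = 0.0)))
    klass <- classifyOffTarget(nm[, "toTest"], nm[, "toGold"], hqThreshold)
    offDf <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(off)),
      start = GenomicRanges::start(off) - 1L,
      end = GenomicRanges::end(off),
      pairing = off$pairing,
      score = off$score,
      nMismFwd = ifelse(off$leftRole == "F", off$nMismLeft,
                        ifelse(off$rightRole == "F", off$nMismRight, NA)),
      nMismRev = ifelse(off$rightRole == "R", off$nMismRight,
                        ifelse(off$leftRole == "R", off$nMismLeft, NA)),
      nmToTest = unname(nm[, "toTest"]),
      nmToGold = unname(nm[, "toGold"]),
      class = klass,
      row.names = NULL)
  } else {
    offDf <- data.frame(
      chrom = character(0), start = integer(0), end = integer(0),
      pairing = character(0), score = integer(0),
      nMismFwd = integer(0), nMismRev = integer(0),
      nmToTest = numeric(0), nmToGold = numeric(0), class = character(0))
  }
  new("SiteAssessment",
      variantId = sub("_(TAS-opt|Relaxed-right|Relaxed-left)$", "",
                      pair@pairName),
      pair = pair,
      ispcrOk = ispcrOk,
      onTarget = if (ispcrOk) hits[onIdx[1]] else emptyHitRanges(),
      offTargets = offDf,
      primerCount = 1L + nrow(offDf),
      concerning = any(offDf$class == "HQ"))
}
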