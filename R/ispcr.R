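#' Query pairings submitted to the in-silico PCR matcher
#'
#' Besides the canonical forward/reverse (FR) reaction, single-primer
#' artifacts are screened by also submitting forward-forward (FF) and
#' reverse-reverse (RR) pairings, so products amplifiable by two copies of
#' the same primer binding convergently are detected.
#'
#' @param pair a [PrimerPair-class]
#' @return data.frame with columns `left`, `right` (primer sequences),
#'   `leftRole`, `rightRole` ("F"/"R"), and `pairing` (FR/FF/RR)
#' @export
buildQueryPairings <- function(pair) {
  stopifnot(is(pair, "PrimerPair"))
  data.frame(
    left = c(pair@fwdSeq, pair@fwdSeq, pair@revSeq),
    right = c(pair@revSeq, pair@fwdSeq, pair@revSeq),
    leftRole = c("F", "F", "R"),
    rightRole = c("R", "F", "R"),
    pairing = c("FR", "FF", "RR"))
}

#' Find mismatch-tolerant primer binding sites genome-wide
#'
#' Seed-and-extend matcher: a locus is examined only where at least one
#' exact `tileSize`-mer of the primer (sampled every `stepSize` along the
#' primer) occurs on the bound strand at the correct diagonal. A candidate
#' locus is accepted as a binding when, aligning the primer gaplessly, (a)
#' the 3'-terminal `minPerfect` bases match exactly, and (b) within the
#' 3'-most `minGood` bases there are at least two matches per mismatch.
#' No indels are modeled: every binding has the primer's length.
#'
#' @param primer primer sequence, 5'->3' (A/C/G/T; length >= tileSize)
#' @param genome named `DNAStringSet` (or FASTA path / `FaFile`)
#' @param params a [MatcherParams-class]
#' @return data.frame with columns `chrom`, `strand`, `start`, `end`
#'   (1-based inclusive footprint on the plus strand), `nMismatch`, and a
#'   list column `mismatches` of 0-based offsets from the primer 5' end
#' @export
findBindings <- function(primer, genome, params = MatcherParams()) {
  genome <- asGenome(genome)
  primer <- toupper(primer)
  L <- nchar(primer)
  if (L < params@tileSize)
    stop("primer (", L, " nt) shorter than tileSize (", params@tileSize, ")")
  tileOffsets <- seq(0L, L - params@tileSize, by = params@stepSize)
  tiles <- substring(primer, tileOffsets + 1L,
                     tileOffsets + params@tileSize)
  primerChars <- strsplit(primer, "")[[1]]
  rcPrimerChars <- strsplit(revComp(primer), "")[[1]]

  out <- list()
  for (chrom in names(genome)) {
    contig <- genome[[chrom]]
    conLen <- length(contig)
    if (conLen < L) next
    for (str in c("+", "-")) {
      cand <- integer(0)
      for (k in seq_along(tiles)) {
        pat <- if (str == "+") tiles[k] else revComp(tiles[k])
        m <- Biostrings::start(Biostrings::matchPattern(
          Biostrings::DNAString(pat), contig, fixed = TRUE))
        if (length(m) == 0L) next
        s <- if (str == "+") m - tileOffsets[k] else
          m - L + tileOffsets[k] + params@tileSize
        cand <- c(cand, s)
      }
      cand <- sort(unique(cand))
      cand <- cand[cand >= 1L & cand + L - 1L <= conLen]
      for (s in cand) {
        site <- as.character(Biostrings::subseq(contig, s, s + L - 1L))
        siteChars <- strsplit(site, "")[[1]]
        # mismatch offsets from the primer 5' end (0-based)
        mism <- if (str == "+") {
          which(siteChars != primerChars) - 1L
        } else {
          (L - which(siteChars != rcPrimerChars))
        }
        mism <- sort(mism)
        if (!bindingAccepted(mism, L, params)) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, strand = str, start = s, end = s + L - 1L,
          nMismatch = length(mism))
        attr(out[[length(out)]], "mism") <- list(mism)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      nMismatch = integer(0),
                      mismatches = I(list())))
  }
  res <- do.call(rbind, out)
  res$mismatches <- I(lapply(out, function(x) attr(x, "mism")[[1]]))
  rownames(res) <- NULL
  res
}

# Acceptance rules shared by the engine and described in MatcherParams:
# exact 3'-terminal minPerfect bases; >= 2 matches per mismatch within the
# 3'-most minGood bases (window truncated to the primer length).
bindingAccepted <- function(mismOffsets, primerLen, params) {
  if (any(mismOffsets >= primerLen - params@minPerfect)) return(FALSE)
  wlen <- min(params@minGood, primerLen)
  mmW <- sum(mismOffsets >= primerLen - wlen)
  (wlen - mmW) >= 2L * mmW
}

#' Pair convergent bindings into candidate PCR products
#'
#' Combines plus-strand bindings of the left query with minus-strand
#' bindings of the right query on the same contig, keeping convergent
#' configurations whose outer span does not exceed `maxSize`. Product
#' coordinates run from the left binding's start to the right binding's
#' end. Divergent (back-to-back) configurations and products spanning
#' contigs are never reported.
#'
#' @param left,right binding data.frames from [findBindings()] for the
#'   left and right query primer
#' @param params a [MatcherParams-class]
#' @return data.frame of unscored hits: `chrom`, `start`, `end` (1-based
#'   inclusive), binding coordinates, and per-side mismatch records
#' @export
pairBindings <- function(left, right, params = MatcherParams()) {
  lp <- left[left$strand == "+", , drop = FALSE]
  rm_ <- right[right$strand == "-", , drop = FALSE]
  if (nrow(lp) == 0L || nrow(rm_) == 0L) return(emptyHits())
  out <- list()
  for (i in seq_len(nrow(lp))) {
    for (j in seq_len(nrow(rm_))) {
      if (lp$chrom[i] != rm_$chrom[j]) next
      prodLen <- rm_$end[j] - lp$start[i] + 1L
      lLen <- lp$end[i] - lp$start[i] + 1L
      rLen <- rm_$end[j] - rm_$start[j] + 1L
      if (prodLen > params@maxSize) next
      if (rm_$start[j] < lp$start[i] || rm_$end[j] < lp$end[i]) next
      if (prodLen < max(lLen, rLen)) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = lp$chrom[i], start = lp$start[i], end = rm_$end[j],
        leftStart = lp$start[i], leftEnd = lp$end[i],
        rightStart = rm_$start[j], rightEnd = rm_$end[j],
        nMismLeft = lp$nMismatch[i], nMismRight = rm_$nMismatch[j])
      attr(out[[length(out)]], "mismL") <- list(lp$mismatches[[i]])
      attr(out[[length(out)]], "mismR") <- list(rm_$mismatches[[j]])
    }
  }
  if (length(out) == 0L) return(emptyHits())
  res <- do.call(rbind, out)
  res$mismLeft <- I(lapply(out, function(x) attr(x, "mismL")[[1]]))
  res$mismRight <- I(lapply(out, function(x) attr(x, "mismR")[[1]]))
  rownames(res) <- NULL
  res
}

emptyHits <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             leftStart = integer(0), leftEnd = integer(0),
             rightStart = integer(0), rightEnd = integer(0),
             nMismLeft = integer(0), nMismRight = integer(0),
             mismLeft = I(list()), mismRight = I(list()))
}

#' Score an in-silico PCR hit on the 0-1000 viability scale
#'
#' A perfect hit (zero mismatches in both primers) scores exactly 1000.
#' Each mismatch reduces the score, with mismatches in the 3'-most
#' `terminalWindow` bases of a primer weighted twice as heavily as 5'
#' mismatches, reflecting their larger effect on extension. Per primer,
#' the weight is `sum(2 if 3'-proximal else 1) / primer length`; the score
#' is `round(1000 * (1 - (wLeft + wRight)/2))`, clipped to [0, 1000].
#' This scheme is this package's documented convention; it is anchored at
#' 1000 for perfect matches and drops mismatch-laden hits below the 750
#' retention threshold quickly.
#'
#' @param mismLeft,mismRight lists of integer vectors of 0-based mismatch
#'   offsets from each primer's 5' end (single vectors are accepted)
#' @param lenLeft,lenRight primer lengths (nt)
#' @param terminalWindow size of the 3'-terminal double-weight zone (nt)
#' @return integer vector of scores in [0, 1000]
#' @export
#' @examples
#' ispcrScore(integer(0), integer(0), 20, 20)      # perfect: 1000
#' ispcrScore(19, integer(0), 20, 20)              # one 3' mismatch
ispcrScore <- function(mismLeft, mismRight, lenLeft, lenRight,
                       terminalWindow = 5L) {
  if (!is.list(mismLeft)) mismLeft <- list(mismLeft)
  if (!is.list(mismRight)) mismRight <- list(mismRight)
  n <- max(length(mismLeft), length(mismRight))
  lenLeft <- rep_len(lenLeft, n)
  lenRight <- rep_len(lenRight, n)
  w <- function(mism, len) {
    vapply(seq_along(mism), function(i) {
      m <- mism[[i]]
      if (length(m) == 0L) return(0)
      sum(ifelse(m >= len[i] - terminalWindow, 2, 1)) / len[i]
    }, 0.0)
  }
  score <- round(1000 * (1 - (w(mismLeft, lenLeft) + w(mismRight, lenRight)) / 2))
  as.integer(pmin(1000, pmax(0, score)))
}

#' Genome-wide in-silico PCR scan for one primer pair
#'
#' Runs the seed-and-extend matcher for both primers on both strands,
#' forms convergent products for all three query pairings (FR in both
#' orientations, FF, RR), scores every hit, attaches the reference
#' product sequence, and flags the on-target hit: the FR hit overlapping
#' the design target with the highest score (ties broken by smallest
#' product).
#'
#' @param pair a [PrimerPair-class]
#' @param genome named `DNAStringSet` (or FASTA path / `FaFile`)
#' @param params a [MatcherParams-class]
#' @return a `GRanges` of hits (1-based inclusive product intervals) with
#'   metadata columns `pairing`, `leftRole`, `rightRole`, binding
#'   coordinates, per-primer mismatch counts and offsets (comma strings),
#'   `score`, `productSeq`, and `isOnTarget`
#' @export
scanPrimerPair <- function(pair, genome, params = MatcherParams()) {
  stopifnot(is(pair, "PrimerPair"))
  genome <- asGenome(genome)
  bF <- findBindings(pair@fwdSeq, genome, params)
  bR <- if (pair@revSeq == pair@fwdSeq) bF else
    findBindings(pair@revSeq, genome, params)

  combos <- list(
    list(pairing = "FR", left = bF, right = bR, lr = "F", rr = "R"),
    list(pairing = "FR", left = bR, right = bF, lr = "R", rr = "F"),
    list(pairing = "FF", left = bF, right = bF, lr = "F", rr = "F"),
    list(pairing = "RR", left = bR, right = bR, lr = "R", rr = "R"))

  rows <- list()
  for (cmb in combos) {
    h <- pairBindings(cmb$left, cmb$right, params)
    if (nrow(h) == 0L) next
    h$pairing <- cmb$pairing
    h$leftRole <- cmb$lr
    h$rightRole <- cmb$rr
    rows[[length(rows) + 1L]] <- h
  }
  if (length(rows) == 0L) return(emptyHitRanges())
  hits <- do.call(rbind, rows)
  # identical product from both FR orientations (palindromic corner case)
  key <- paste(hits$pairing, hits$chrom, hits$start, hits$end,
               hits$leftStart, hits$rightStart, hits$leftRole)
  hits <- hits[!duplicated(key), , drop = FALSE]

  lenL <- hits$leftEnd - hits$leftStart + 1L
  lenR <- hits$rightEnd - hits$rightStart + 1L
  hits$score <- ispcrScore(hits$mismLeft, hits$mismRight, lenL, lenR)
  hits$productSeq <- vapply(seq_len(nrow(hits)), function(i) {
    as.character(Biostrings::subseq(genome[[hits$chrom[i]]],
                                    hits$start[i], hits$end[i]))
  }, "")

  gr <- GenomicRanges::GRanges(
    seqnames = hits$chrom,
    ranges = IRanges::IRanges(hits$start, hits$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    pairName = pair@pairName,
    pairing = hits$pairing,
    leftRole = hits$leftRole, rightRole = hits$rightRole,
    leftStart = hits$leftStart, leftEnd = hits$leftEnd,
    rightStart = hits$rightStart, rightEnd = hits$rightEnd,
    nMismLeft = hits$nMismLeft, nMismRight = hits$nMismRight,
    mismLeft = vapply(hits$mismLeft, paste, "", collapse = ","),
    mismRight = vapply(hits$mismRight, paste, "", collapse = ","),
    score = hits$score,
    productSeq = hits$productSeq,
    isOnTarget = FALSE)

  onCand <- which(gr$pairing == "FR" &
                  as.character(GenomicRanges::seqnames(gr)) == pair@chrom &
                  GenomicRanges::start(gr) <= pair@targetPos &
                  GenomicRanges::end(gr) >= pair@targetPos)
  if (length(onCand) > 0L) {
    ord <- onCand[order(-gr$score[onCand], GenomicRanges::width(gr)[onCand])]
    gr$isOnTarget[ord[1]] <- TRUE
  }
  sort(gr, ignore.strand = TRUE)
}

emptyHitRanges <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    pairName = character(0), pairing = character(0),
    leftRole = character(0), rightRole = character(0),
    leftStart = integer(0), leftEnd = integer(0),
    rightStart = integer(0), rightEnd = integer(0),
    nMismLeft = integer(0), nMismRight = integer(0),
    mismLeft = character(0), mismRight = character(0),
    score = integer(0), productSeq = character(0),
    isOnTarget = logical(0))
  gr
}

#' Write in-silico PCR products as FASTA
#'
#' One record per hit; the header encodes the 0-based half-open product
#' interval, the query pairing, the pair name, and the score:
#' `>chrom:start-end pairing=FR pair=<name> score=1000`.
#'
#' @param hits a hit `GRanges` from [scanPrimerPair()]
#' @param path output file path
#' @return the path, invisibly
#' @export
writeProductsFasta <- function(hits, path) {
  if (length(hits) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  headers <- sprintf("%s:%d-%d pairing=%s pair=%s score=%d",
                     as.character(GenomicRanges::seqnames(hits)),
                     GenomicRanges::start(hits) - 1L,
                     GenomicRanges::end(hits),
                     hits$pairing, hits$pairName, hits$score)
  seqs <- Biostrings::DNAStringSet(hits$productSeq)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write in-silico PCR hits as BED
#'
#' Standard 5-column BED (0-based half-open): chrom, start, end, name
#' (`<pairName>|<pairing>`), score.
#'
#' @param hits a hit `GRanges` from [scanPrimerPair()]
#' @param path output file path
#' @return the path, invisibly
#' @export
writeHitsBed <- function(hits, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(hits)),
    start = GenomicRanges::start(hits) - 1L,
    end = GenomicRanges::end(hits),
    name = if (length(hits)) paste0(hits$pairName, "|", hits$pairing)
           else character(0),
    score = hits$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
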