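# Internal helpers shared across modules.

# Reverse complement for plain character vectors (A/C/G/T/N only).
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Fraction of G/C in a vector of sequences, as percent.
gcPercent <- function(x) {
  gc <- vapply(strsplit(x, ""), function(ch) sum(ch %in% c("G", "C")), 0L)
  100 * gc / nchar(x)
}

# Longest homopolymer run per sequence.
maxHomopolymerRun <- function(x) {
  vapply(strsplit(x, ""), function(ch) {
    if (length(ch) == 0L) return(0L)
    max(rle(ch)$lengths)
  }, 0L)
}

# Natural chromosome rank: numeric names first (by value), then X, Y, M/MT,
# then everything else lexicographically. Names are used verbatim otherwise;
# a leading "chr" is ignored only for ordering.
chromRank <- function(chrom) {
  core <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(core))
  rank <- numeric(length(chrom))
  isNum <- !is.na(num)
  rank[isNum] <- num[isNum]
  special <- c(X = 1e6, Y = 1e6 + 1, M = 1e6 + 2, MT = 1e6 + 2)
  isSpec <- !isNum & core %in% names(special)
  rank[isSpec] <- special[core[isSpec]]
  other <- !isNum & !isSpec
  if (any(other)) {
    lex <- match(core[other], sort(unique(core[other])))
    rank[other] <- 2e6 + lex
  }
  rank
}

# Coerce a reference argument to a named DNAStringSet. Accepts a
# DNAStringSet, a file path to a FASTA, or an Rsamtools::FaFile.
asGenome <- function(reference) {
  if (is(reference, "DNAStringSet")) {
    ref <- reference
  } else if (is(reference, "FaFile")) {
    ref <- Biostrings::readDNAStringSet(Rsamtools::path(reference))
  } else if (is.character(reference) && length(reference) == 1L) {
    ref <- Biostrings::readDNAStringSet(reference)
  } else {
    stop("reference must be a DNAStringSet, FaFile, or FASTA path")
  }
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}
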