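# Deterministic synthetic-genome fixtures: miniature references with
# planted target templates and off-target copies at controlled divergence,
# so every pipeline stage runs without downloading a real genome.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  }
  set.seed(seed)
  expr
}

#' Simulate a miniature reference genome
#'
#' Contigs are i.i.d. uniform A/C/G/T (optionally GC-biased) at a fixed
#' seed, so the same spec always yields byte-identical sequence. Uniform
#' composition keeps k-mer occurrences near-unique at the 10 kb-2 Mb
#' scales these fixtures use, which makes random background designable
#' and off-target-free except where copies are planted explicitly.
#'
#' @param contigs named integer vector of contig lengths (bp)
#' @param seed RNG seed
#' @param gc target GC fraction of the background
#' @return a named `DNAStringSet`
#' @export
#' @examples
#' simulateGenome(c(chr1 = 1000), seed = 7)
simulateGenome <- function(contigs = c(chr1 = 50000L), seed = 1L, gc = 0.5) {
  stopifnot(!is.null(names(contigs)), all(contigs > 0))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- withSeed(seed, lapply(contigs, function(len) {
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = "")
  }))
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(contigs)
  genome
}

#' Simulate a target-site table over a genome
#'
#' Draws target positions uniformly per contig, keeping a margin from the
#' contig ends so the full design window fits. Deterministic in the seed.
#'
#' @param genome a named `DNAStringSet`
#' @param n number of targets per contig (recycled over contigs)
#' @param proj project label for all rows
#' @param margin minimum distance from either contig end (bp)
#' @param seed RNG seed
#' @return data.frame with columns `CHROM`, `POS`, `PROJ`
#' @export
simulateTargets <- function(genome, n = 1L, proj = "sim", margin = 600L,
                            seed = 1L) {
  lens <- Biostrings::width(genome)
  n <- rep_len(n, length(genome))
  withSeed(seed, {
    rows <- lapply(seq_along(genome), function(i) {
      lo <- margin + 1L
      hi <- lens[i] - margin
      if (hi < lo) stop("contig ", names(genome)[i],
                        " too short for margin ", margin)
      data.frame(CHROM = names(genome)[i],
                 POS = sort(sample(lo:hi, n[i])),
                 PROJ = proj)
    })
    do.call(rbind, rows)
  })
}

#' Plant a copy of an amplicon elsewhere in the genome
#'
#' Copies the source interval (typically a realized on-target amplicon) to
#' a destination locus, overwriting the background there, with a
#' controlled fraction of substitution mutations. `divergence` is the
#' exact fraction of copied bases mutated: `round(divergence * length)`
#' distinct positions are substituted to a different base. With
#' `preservePrimerSites = TRUE` the first `fwdLen` and last `revLen`
#' bases (the primer footprints) are never mutated, so binding survival
#' is controlled independently of interior amplicon similarity. The
#' destination must not overlap the source.
#'
#' @param genome a named `DNAStringSet`
#' @param chrom,start,end source interval, 1-based inclusive
#' @param destChrom,destStart destination locus, 1-based
#' @param divergence fraction of copied bases to substitute, in [0, 1]
#' @param preservePrimerSites keep primer footprints mutation-free
#' @param fwdLen,revLen primer footprint lengths (bp) when preserving
#' @param mode "full" copies the whole amplicon; "primerOnly" writes only
#'   the two primer footprints at the correct spacing, leaving the
#'   interior as background
#' @param seed RNG seed for mutation placement
#' @return list with elements `genome` (modified), `destStart`, `destEnd`
#'   (1-based inclusive), and `mutated` (1-based positions on `destChrom`
#'   that were substituted)
#' @export
plantOffTarget <- function(genome, chrom, start, end, destChrom, destStart,
                           divergence = 0, preservePrimerSites = TRUE,
                           fwdLen = 0L, revLen = 0L,
                           mode = c("full", "primerOnly"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(divergence >= 0, divergence <= 1)
  src <- as.character(Biostrings::subseq(genome[[chrom]], start, end))
  L <- nchar(src)
  destEnd <- destStart + L - 1L
  if (destEnd > length(genome[[destChrom]]) || destStart < 1L)
    stop("destination interval outside contig ", destChrom)
  if (destChrom == chrom && destStart <= end && destEnd >= start)
    stop("destination overlaps the source interval")

  copy <- strsplit(src, "")[[1]]
  mutable <- seq_len(L)
  if (preservePrimerSites && (fwdLen > 0L || revLen > 0L)) {
    foot <- c(seq_len(fwdLen), if (revLen > 0L) (L - revLen + 1L):L)
    mutable <- setdiff(mutable, foot)
  }
  nMut <- round(divergence * L)
  if (nMut > length(mutable))
    stop("divergence too high for the mutable interior")
  mutIdx <- integer(0)
  if (nMut > 0L) {
    mutIdx <- withSeed(seed, {
      idx <- sort(sample(mutable, nMut))
      copy[idx] <- vapply(copy[idx], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      idx
    })
  }
  if (mode == "primerOnly") {
    keep <- c(seq_len(fwdLen), if (revLen > 0L) (L - revLen + 1L):L)
    background <- strsplit(as.character(
      Biostrings::subseq(genome[[destChrom]], destStart, destEnd)), "")[[1]]
    merged <- background
    merged[keep] <- copy[keep]
    copy <- merged
    mutIdx <- intersect(mutIdx, keep)
  }
  newContig <- Biostrings::replaceAt(
    genome[[destChrom]],
    IRanges::IRanges(destStart, destEnd),
    Biostrings::DNAStringSet(paste(copy, collapse = "")))
  genome[[destChrom]] <- newContig
  list(genome = genome, destStart = destStart, destEnd = destEnd,
       mutated = destStart - 1L + mutIdx)
}

#' Substitute single bases in a genome
#'
#' Replaces each listed position with a different base (deterministic in
#' the seed). Useful for breaking a planted primer footprint at its 3'
#' terminus so the matcher's exact-terminus rule rejects it.
#'
#' @param genome a named `DNAStringSet`
#' @param chrom contig name
#' @param positions 1-based positions to substitute
#' @param seed RNG seed
#' @return the modified `DNAStringSet`
#' @export
substituteBases <- function(genome, chrom, positions, seed = 1L) {
  contig <- genome[[chrom]]
  bases <- withSeed(seed, vapply(positions, function(p) {
    orig <- as.character(Biostrings::subseq(contig, p, p))
    sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
  }, ""))
  genome[[chrom]] <- Biostrings::replaceAt(
    contig, IRanges::IRanges(positions, positions),
    Biostrings::DNAStringSet(bases))
  genome
}

#' Write a fixture to disk
#'
#' Emits the genome as FASTA with a sidecar `.fai` index, the target table
#' as CSV (header `CHROM,POS,PROJ` plus any extra columns), and an
#' optional JSON manifest describing planted features.
#'
#' @param genome a named `DNAStringSet`
#' @param targets data.frame with `CHROM`, `POS`, `PROJ`
#' @param dir output directory (created if needed)
#' @param manifest optional list serialized to `manifest.json`
#' @return named character vector of written paths
#' @export
writeFixture <- function(genome, targets, dir, manifest = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, fa)
  Rsamtools::indexFa(fa)
  csv <- file.path(dir, "targets.csv")
  utils::write.csv(targets, csv, row.names = FALSE, quote = FALSE)
  paths <- c(fasta = fa, index = paste0(fa, ".fai"), targets = csv)
  if (!is.null(manifest)) {
    mf <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, manifest = mf)
  }
  paths
}
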