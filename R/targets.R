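#' Build the canonical variant identifier for a target site
#'
#' The identifier joins the project label, contig, and 1-based position
#' with underscores: `PROJ_CHROM_POS`, e.g. `clinvar_1_944041`. It keys
#' every downstream table and is embedded in primer names.
#'
#' @param proj project label (no whitespace)
#' @param chrom contig name, used verbatim
#' @param pos 1-based position (integer or integer-valued)
#' @return character vector of identifiers
#' @export
#' @examples
#' makeVariantId("clinvar", "1", 944041)
makeVariantId <- function(proj, chrom, pos) {
  stopifnot(!any(grepl("\\s", proj)))
  paste(proj, chrom, format(as.integer(pos), scientific = FALSE, trim = TRUE),
        sep = "_")
}

#' Read a target-site table
#'
#' Parses a comma-delimited UTF-8 table with the required (case-sensitive)
#' header names `CHROM`, `POS`, and `PROJ`. Any extra columns are retained
#' and passed through to the final report. Input row order is preserved.
#' Rows that duplicate a (CHROM, POS, PROJ) triple would collide on
#' `variant_ID` and are collapsed to the first occurrence with a warning.
#'
#' @param path path to the CSV file
#' @return a data.frame with columns `CHROM` (character), `POS` (integer),
#'   `PROJ` (character), a derived `variant_ID`, plus any extra input
#'   columns
#' @export
readTargetTable <- function(path) {
  if (!file.exists(path)) stop("target table not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  required <- c("CHROM", "POS", "PROJ")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    stop("target table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(tab) == 0L) {
    tab$POS <- integer(0)
    tab$variant_ID <- character(0)
    return(tab)
  }
  posNum <- suppressWarnings(as.numeric(tab$POS))
  bad <- which(is.na(posNum) | posNum != floor(posNum) | posNum < 1)
  if (length(bad) > 0L)
    stop("non-integer POS value '", tab$POS[bad[1]], "' in row ", bad[1])
  tab$POS <- as.integer(posNum)
  tab$variant_ID <- makeVariantId(tab$PROJ, tab$CHROM, tab$POS)
  dup <- duplicated(tab$variant_ID)
  if (any(dup)) {
    warning("collapsed ", sum(dup), " duplicate target row(s): ",
            paste(unique(tab$variant_ID[dup]), collapse = ", "))
    tab <- tab[!dup, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Extract a template window around a target site
#'
#' Slices the reference around a 1-based position: the window covers
#' `[pos - 1 - flank, pos + flank)` in 0-based half-open coordinates,
#' clipped to the contig bounds, and is returned uppercased as a
#' [TemplateWindow-class]. The default flank of 500 bp accommodates the
#' largest (relaxed, 500 bp) amplicon geometry on either side of the
#' target.
#'
#' @param reference a named `DNAStringSet`, an `Rsamtools::FaFile`, or a
#'   FASTA file path
#' @param chrom contig name (must exist in the reference)
#' @param pos 1-based target position
#' @param proj project label used to derive the variant identifier
#' @param flank bases requested on each side of the target
#' @return a [TemplateWindow-class]
#' @export
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 50),
#'                                                collapse = "")))
#' extractWindow(ref, "chr1", 100, proj = "p", flank = 20)
setGeneric("extractWindow",
  function(reference, chrom, pos, proj = "site", flank = 500L)
    standardGeneric("extractWindow"))

#' @rdname extractWindow
setMethod("extractWindow", "DNAStringSet",
  function(reference, chrom, pos, proj = "site", flank = 500L) {
    if (!chrom %in% names(reference))
      stop("contig '", chrom, "' not in reference; available: ",
           paste(names(reference), collapse = ", "))
    pos <- as.integer(pos)
    flank <- as.integer(flank)
    len <- Biostrings::width(reference)[match(chrom, names(reference))]
    if (pos < 1L || pos > len)
      stop("pos ", pos, " outside contig ", chrom, " (length ", len, ")")
    from <- max(1L, pos - flank)
    to <- min(len, pos + flank)
    seq <- toupper(as.character(Biostrings::subseq(reference[[chrom]],
                                                   from, to)))
    new("TemplateWindow",
        chrom = chrom, pos = pos, proj = proj,
        variantId = makeVariantId(proj, chrom, pos),
        seq = seq, windowStart = from - 1L, targetOffset = pos - from)
  })

#' @rdname extractWindow
setMethod("extractWindow", "FaFile",
  function(reference, chrom, pos, proj = "site", flank = 500L) {
    idx <- Rsamtools::scanFaIndex(reference)
    contigs <- as.character(GenomeInfoDb::seqnames(idx))
    if (!chrom %in% contigs)
      stop("contig '", chrom, "' not in reference; available: ",
           paste(contigs, collapse = ", "))
    pos <- as.integer(pos)
    flank <- as.integer(flank)
    len <- GenomicRanges::width(idx)[match(chrom, contigs)]
    if (pos < 1L || pos > len)
      stop("pos ", pos, " outside contig ", chrom, " (length ", len, ")")
    from <- max(1L, pos - flank)
    to <- min(len, pos + flank)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(from, to))
    seq <- toupper(as.character(Rsamtools::scanFa(reference, gr)[[1]]))
    new("TemplateWindow",
        chrom = chrom, pos = pos, proj = proj,
        variantId = makeVariantId(proj, chrom, pos),
        seq = seq, windowStart = from - 1L, targetOffset = pos - from)
  })

#' @rdname extractWindow
setMethod("extractWindow", "character",
  function(reference, chrom, pos, proj = "site", flank = 500L) {
    extractWindow(asGenome(reference), chrom, pos, proj, flank)
  })
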