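#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

setClassUnion("PrimerPairOrNULL", "NULL")

#' TemplateWindow: a local reference slice around one target site
#'
#' Holds the uppercase template sequence extracted around a single genomic
#' target position, together with the coordinate bookkeeping needed to map
#' window offsets back to the contig. Coordinates follow the VCF/BED mix
#' used throughout the package: `pos` is 1-based, `windowStart` is the
#' 0-based half-open start of the slice on the contig, and `targetOffset`
#' is the 0-based index of the target base within `seq`, so that
#' `windowStart + targetOffset + 1 == pos`.
#'
#' @slot chrom contig name, stored verbatim (no "chr" munging)
#' @slot pos 1-based target coordinate on `chrom`
#' @slot proj project label
#' @slot variantId derived identifier `PROJ_CHROM_POS`
#' @slot seq uppercase template sequence (A/C/G/T/N)
#' @slot windowStart 0-based half-open start of `seq` on `chrom`
#' @slot targetOffset 0-based index of the target base within `seq`
#' @exportClass TemplateWindow
setClass("TemplateWindow",
  representation(
    chrom = "character",
    pos = "integer",
    proj = "character",
    variantId = "character",
    seq = "character",
    windowStart = "integer",
    targetOffset = "integer"
  )
)

setValidity("TemplateWindow", function(object) {
  msg <- NULL
  if (object@pos < 1L) msg <- c(msg, "pos must be >= 1")
  if (grepl("[^ACGTN]", object@seq))
    msg <- c(msg, "seq may contain only A/C/G/T/N")
  if (object@targetOffset < 0L || object@targetOffset >= nchar(object@seq))
    msg <- c(msg, "targetOffset outside seq")
  if (object@windowStart + object@targetOffset + 1L != object@pos)
    msg <- c(msg, "windowStart + targetOffset + 1 must equal pos")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "TemplateWindow", function(object) {
  cat("TemplateWindow ", object@variantId, "\n",
      "  ", object@chrom, ":", object@pos,
      " (window ", object@windowStart, "-",
      object@windowStart + nchar(object@seq),
      ", target offset ", object@targetOffset, ")\n",
      "  seq: ", nchar(object@seq), " bp\n", sep = "")
})

#' DesignGeometry: amplicon geometry constraints for one design mode
#'
#' The three TAS design modes differ only in which primer keeps the strict
#' 60-100 bp distance-to-target constraint and how large the product may
#' grow. `TAS_OPT` anchors both primer 3' ends 60-100 bp from the target
#' with an optimal 190 bp product, so the target is covered by both mates
#' of a 150 bp paired-end read. `RELAXED_RIGHT` keeps the forward (left)
#' primer anchored and lets the product grow to 500 bp on the right;
#' `RELAXED_LEFT` mirrors it.
#'
#' @slot mode one of "TAS_OPT", "RELAXED_RIGHT", "RELAXED_LEFT"
#' @slot label mode label used in primer names
#' @slot anchor which side keeps the distance constraint: both/left/right
#' @slot distMin,distMax allowed 3'-end-to-target distance (bp) on anchored sides
#' @slot productMin,productOpt,productMax product size range and optimum (bp)
#' @exportClass DesignGeometry
setClass("DesignGeometry",
  representation(
    mode = "character",
    label = "character",
    anchor = "character",
    distMin = "integer",
    distMax = "integer",
    productMin = "integer",
    productOpt = "integer",
    productMax = "integer"
  )
)

setValidity("DesignGeometry", function(object) {
  msg <- NULL
  if (!object@mode %in% c("TAS_OPT", "RELAXED_RIGHT", "RELAXED_LEFT"))
    msg <- c(msg, "unknown mode")
  if (!object@anchor %in% c("both", "left", "right"))
    msg <- c(msg, "anchor must be both/left/right")
  if (object@mode != "TAS_OPT" && object@anchor == "both")
    msg <- c(msg, "relaxed modes anchor exactly one side")
  if (object@productMax < object@productOpt)
    msg <- c(msg, "productMax must be >= productOpt")
  if (object@distMin < 1L || object@distMax < object@distMin)
    msg <- c(msg, "invalid distance range")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "DesignGeometry", function(object) {
  cat("DesignGeometry ", object@label, " (anchor: ", object@anchor, ")\n",
      "  3'-end distance ", object@distMin, "-", object@distMax, " bp; ",
      "product ", object@productMin, "-", object@productMax,
      " bp (opt ", object@productOpt, ")\n", sep = "")
})

#' DesignSpec: fully resolved constraints for one design attempt
#'
#' Produced by [buildDesignSpec()] from a [TemplateWindow-class] and a
#' [DesignGeometry-class]; holds the per-side 3'-end distance windows and
#' primer quality settings the engine enumerates against. Left/right are in
#' template (plus-strand) orientation.
#'
#' @slot mode,label design mode and its name label
#' @slot leftDistMin,leftDistMax forward primer 3'-end distance range (bp)
#' @slot rightDistMin,rightDistMax reverse primer 3'-end distance range (bp)
#' @slot productMin,productOpt,productMax product size constraints (bp)
#' @slot primerLenMin,primerLenMax allowed primer lengths (nt)
#' @slot tmMin,tmOpt,tmMax melting temperature window (Celsius)
#' @slot gcMin,gcMax allowed GC fraction bounds (percent)
#' @slot maxHomopolymer longest allowed single-base run (nt)
#' @slot symmetric whether the target placement penalty is applied
#' @exportClass DesignSpec
setClass("DesignSpec",
  representation(
    mode = "character",
    label = "character",
    leftDistMin = "integer",
    leftDistMax = "integer",
    rightDistMin = "integer",
    rightDistMax = "integer",
    productMin = "integer",
    productOpt = "integer",
    productMax = "integer",
    primerLenMin = "integer",
    primerLenMax = "integer",
    tmMin = "numeric",
    tmOpt = "numeric",
    tmMax = "numeric",
    gcMin = "numeric",
    gcMax = "numeric",
    maxHomopolymer = "integer",
    symmetric = "logical"
  )
)

setMethod("show", "DesignSpec", function(object) {
  cat("DesignSpec [", object@label, "]\n",
      "  left 3' distance  ", object@leftDistMin, "-", object@leftDistMax, " bp\n",
      "  right 3' distance ", object@rightDistMin, "-", object@rightDistMax, " bp\n",
      "  product ", object@productMin, "-", object@productMax,
      " bp (opt ", object@productOpt, ")\n", sep = "")
})

#' PrimerPair: one designed forward/reverse primer pair
#'
#' Sequences are 5' to 3'. `ampliconStart`/`ampliconEnd` are 0-based
#' half-open genomic coordinates of the predicted product, so
#' `ampliconEnd - ampliconStart == predictedProduct` and the target base
#' lies strictly inside the interval.
#'
#' @slot pairName pair identifier `<variant_id>_<mode-label>`
#' @slot fwdName,revName primer names with `_F`/`_R` suffixes
#' @slot fwdSeq,revSeq primer sequences, 5'->3', A/C/G/T only
#' @slot fwdTm,revTm nearest-neighbor melting temperatures (Celsius)
#' @slot mode design mode that produced the pair
#' @slot chrom contig of the predicted amplicon
#' @slot targetPos 1-based target position the pair was designed for
#' @slot predictedProduct predicted product length (bp)
#' @slot ampliconStart,ampliconEnd 0-based half-open product interval
#' @exportClass PrimerPair
setClass("PrimerPair",
  representation(
    pairName = "character",
    fwdName = "character",
    revName = "character",
    fwdSeq = "character",
    revSeq = "character",
    fwdTm = "numeric",
    revTm = "numeric",
    mode = "character",
    chrom = "character",
    targetPos = "integer",
    predictedProduct = "integer",
    ampliconStart = "integer",
    ampliconEnd = "integer"
  )
)

setValidity("PrimerPair", function(object) {
  msg <- NULL
  if (nchar(object@fwdSeq) == 0L || nchar(object@revSeq) == 0L)
    msg <- c(msg, "primer sequences must be non-empty")
  if (grepl("[^ACGT]", object@fwdSeq) || grepl("[^ACGT]", object@revSeq))
    msg <- c(msg, "primer sequences must be A/C/G/T only")
  if (object@ampliconEnd - object@ampliconStart != object@predictedProduct)
    msg <- c(msg, "ampliconEnd - ampliconStart must equal predictedProduct")
  t0 <- object@targetPos - 1L
  if (t0 < object@ampliconStart || t0 >= object@ampliconEnd)
    msg <- c(msg, "target position must lie inside the amplicon interval")
  if (is.null(msg)) TRUE else msg
})

setIs("PrimerPair", "PrimerPairOrNULL")

setMethod("show", "PrimerPair", function(object) {
  cat("PrimerPair ", object@pairName, " [", object@mode, "]\n",
      "  F: ", object@fwdSeq, " (Tm ", round(object@fwdTm, 1), ")\n",
      "  R: ", object@revSeq, " (Tm ", round(object@revTm, 1), ")\n",
      "  product ", object@predictedProduct, " bp at ", object@chrom, ":",
      object@ampliconStart, "-", object@ampliconEnd, "\n", sep = "")
})

#' DesignOutcome: design result for one target site
#'
#' @slot chrom,pos,proj,variantId the site the outcome belongs to
#' @slot pair the retained [PrimerPair-class], or NULL when all modes failed
#' @slot attemptedModes ordered prefix of TAS_OPT, RELAXED_RIGHT, RELAXED_LEFT
#' @slot primer3Ok TRUE iff a viable pair was designed
#' @exportClass DesignOutcome
setClass("DesignOutcome",
  representation(
    chrom = "character",
    pos = "integer",
    proj = "character",
    variantId = "character",
    pair = "PrimerPairOrNULL",
    attemptedModes = "character",
    primer3Ok = "logical"
  )
)

setValidity("DesignOutcome", function(object) {
  msg <- NULL
  if (object@primer3Ok != !is.null(object@pair))
    msg <- c(msg, "primer3Ok must be TRUE iff a pair is present")
  order <- c("TAS_OPT", "RELAXED_RIGHT", "RELAXED_LEFT")
  k <- length(object@attemptedModes)
  if (k < 1L || k > 3L || !identical(object@attemptedModes, order[seq_len(k)]))
    msg <- c(msg, "attemptedModes must be a prefix of TAS_OPT, RELAXED_RIGHT, RELAXED_LEFT")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "DesignOutcome", function(object) {
  cat("DesignOutcome ", object@variantId, ": ",
      if (object@primer3Ok) object@pair@mode else "design failed",
      " (attempted ", paste(object@attemptedModes, collapse = " > "), ")\n",
      sep = "")
})

#' MatcherParams: seed-and-extend in-silico PCR matcher settings
#'
#' Defaults mirror the mismatch-tolerant screening configuration used for
#' TAS panel design: `minPerfect = 1` (exact match required at the primer
#' 3' terminus), `minGood = 15` (within the 3'-most 15 bases there must be
#' at least two matches per mismatch), `tileSize = 11` with `stepSize = 5`
#' (an exact 11-mer seed sampled every 5 bases must hit the locus), and
#' `maxSize = 800` (largest reported product).
#'
#' @slot minPerfect,minGood,tileSize,stepSize,maxSize see description
#' @exportClass MatcherParams
setClass("MatcherParams",
  representation(
    minPerfect = "integer",
    minGood = "integer",
    tileSize = "integer",
    stepSize = "integer",
    maxSize = "integer"
  )
)

setValidity("MatcherParams", function(object) {
  msg <- NULL
  vals <- c(object@minPerfect, object@minGood, object@tileSize,
            object@stepSize, object@maxSize)
  if (any(vals < 1L)) msg <- c(msg, "all parameters must be positive")
  if (object@tileSize < object@stepSize)
    msg <- c(msg, "tileSize must be >= stepSize")
  if (is.null(msg)) TRUE else msg
})

#' @param minPerfect minimum exact match at the primer 3' end (bp)
#' @param minGood 3'-terminal window needing two matches per mismatch (bp)
#' @param tileSize exact seed size that triggers an alignment (bp)
#' @param stepSize spacing between sampled seeds (bp)
#' @param maxSize maximum reported PCR product size (bp)
#' @return a `MatcherParams` object
#' @rdname MatcherParams-class
#' @export
#' @examples
#' MatcherParams()
MatcherParams <- function(minPerfect = 1L, minGood = 15L, tileSize = 11L,
                          stepSize = 5L, maxSize = 800L) {
  new("MatcherParams",
      minPerfect = as.integer(minPerfect), minGood = as.integer(minGood),
      tileSize = as.integer(tileSize), stepSize = as.integer(stepSize),
      maxSize = as.integer(maxSize))
}

setMethod("show", "MatcherParams", function(object) {
  cat("MatcherParams: minPerfect=", object@minPerfect,
      " minGood=", object@minGood, " tileSize=", object@tileSize,
      " stepSize=", object@stepSize, " maxSize=", object@maxSize, "\n",
      sep = "")
})

#' SiteAssessment: specificity verdict for one designed site
#'
#' @slot variantId site identifier
#' @slot pair the assessed [PrimerPair-class] (or NULL)
#' @slot ispcrOk TRUE iff the on-target product was recovered in silico
#' @slot onTarget `GRanges` of length 0 or 1 holding the on-target hit
#' @slot offTargets data.frame of off-target calls (coordinates, score,
#'   per-primer mismatch counts, both normalized matches, HQ/LQ class)
#' @slot primerCount 1 + number of retained off-targets
#' @slot concerning TRUE iff any off-target is classified HQ
#' @exportClass SiteAssessment
setClass("SiteAssessment",
  representation(
    variantId = "character",
    pair = "PrimerPairOrNULL",
    ispcrOk = "logical",
    onTarget = "ANY",
    offTargets = "data.frame",
    primerCount = "integer",
    concerning = "logical"
  )
)

setValidity("SiteAssessment", function(object) {
  msg <- NULL
  if (object@primerCount != 1L + nrow(object@offTargets))
    msg <- c(msg, "primerCount must equal 1 + number of off-targets")
  if (nrow(object@offTargets) > 0L &&
      object@concerning != any(object@offTargets$class == "HQ"))
    msg <- c(msg, "concerning must reflect presence of an HQ off-target")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SiteAssessment", function(object) {
  cat("SiteAssessment ", object@variantId, "\n",
      "  ISPCR ok: ", object@ispcrOk,
      "; primer count: ", object@primerCount,
      "; concerning: ", object@concerning, "\n", sep = "")
  if (nrow(object@offTargets) > 0L) {
    tab <- table(object@offTargets$class)
    cat("  off-targets:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  }
})
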