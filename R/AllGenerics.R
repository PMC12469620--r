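#' Accessors for ampliScreen S4 objects
#'
#' Small accessor family so downstream code never touches slots directly:
#' `variantId()` returns the site identifier, `primerPair()` the retained
#' pair (or NULL), `windowSeq()` the template sequence, `targetOffset()`
#' the 0-based target index within a window, `primerCount()` and
#' `isConcerning()` the headline verdict of an assessment, and
#' `offTargets()` its per-off-target detail table.
#'
#' @param x an ampliScreen object
#' @return see the individual generic descriptions
#' @name accessors
#' @examples
#' w <- new("TemplateWindow", chrom = "chr1", pos = 5L, proj = "p",
#'          variantId = "p_chr1_5", seq = "ACGTACGTA", windowStart = 0L,
#'          targetOffset = 4L)
#' variantId(w)
#' targetOffset(w)
NULL

#' @rdname accessors
#' @export
setGeneric("variantId", function(x) standardGeneric("variantId"))
#' @rdname accessors
#' @export
setGeneric("primerPair", function(x) standardGeneric("primerPair"))
#' @rdname accessors
#' @export
setGeneric("windowSeq", function(x) standardGeneric("windowSeq"))
#' @rdname accessors
#' @export
setGeneric("targetOffset", function(x) standardGeneric("targetOffset"))
#' @rdname accessors
#' @export
setGeneric("primerCount", function(x) standardGeneric("primerCount"))
#' @rdname accessors
#' @export
setGeneric("isConcerning", function(x) standardGeneric("isConcerning"))
#' @rdname accessors
#' @export
setGeneric("offTargets", function(x) standardGeneric("offTargets"))
#' @rdname accessors
#' @export
setGeneric("attemptedModes", function(x) standardGeneric("attemptedModes"))

#' @rdname accessors
setMethod("variantId", "TemplateWindow", function(x) x@variantId)
#' @rdname accessors
setMethod("variantId", "DesignOutcome", function(x) x@variantId)
#' @rdname accessors
setMethod("variantId", "SiteAssessment", function(x) x@variantId)

#' @rdname accessors
setMethod("primerPair", "DesignOutcome", function(x) x@pair)
#' @rdname accessors
setMethod("primerPair", "SiteAssessment", function(x) x@pair)

#' @rdname accessors
setMethod("windowSeq", "TemplateWindow", function(x) x@seq)
#' @rdname accessors
setMethod("targetOffset", "TemplateWindow", function(x) x@targetOffset)

#' @rdname accessors
setMethod("primerCount", "SiteAssessment", function(x) x@primerCount)
#' @rdname accessors
setMethod("isConcerning", "SiteAssessment", function(x) x@concerning)
#' @rdname accessors
setMethod("offTargets", "SiteAssessment", function(x) x@offTargets)

#' @rdname accessors
setMethod("attemptedModes", "DesignOutcome", function(x) x@attemptedModes)
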