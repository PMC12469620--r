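#' Amplicon design geometries for 150 bp paired-end TAS
#'
#' `tasOptGeometry()` is the strict geometry: both primer 3' ends must sit
#' 60-100 bp from the target so both mates of a 150 bp paired-end read
#' cover it, with the product optimized at 190 bp. `relaxedRightGeometry()`
#' keeps the forward primer anchored at that distance but frees the reverse
#' primer up to a 500 bp product; `relaxedLeftGeometry()` mirrors it. The
#' waterfall tries them in exactly that order.
#'
#' @param distMin,distMax anchored 3'-end distance to target (bp)
#' @param productMin,productOpt,productMax product size constraints (bp)
#' @return a [DesignGeometry-class]
#' @export
#' @examples
#' tasOptGeometry()
#' relaxedRightGeometry()
tasOptGeometry <- function(distMin = 60L, distMax = 100L,
                           productMin = 150L, productOpt = 190L,
                           productMax = 200L) {
  new("DesignGeometry", mode = "TAS_OPT", label = "TAS-opt", anchor = "both",
      distMin = as.integer(distMin), distMax = as.integer(distMax),
      productMin = as.integer(productMin), productOpt = as.integer(productOpt),
      productMax = as.integer(productMax))
}

#' @rdname tasOptGeometry
#' @export
relaxedRightGeometry <- function(distMin = 60L, distMax = 100L,
                                 productMin = 120L, productOpt = 190L,
                                 productMax = 500L) {
  new("DesignGeometry", mode = "RELAXED_RIGHT", label = "Relaxed-right",
      anchor = "left",
      distMin = as.integer(distMin), distMax = as.integer(distMax),
      productMin = as.integer(productMin), productOpt = as.integer(productOpt),
      productMax = as.integer(productMax))
}

#' @rdname tasOptGeometry
#' @export
relaxedLeftGeometry <- function(distMin = 60L, distMax = 100L,
                                productMin = 120L, productOpt = 190L,
                                productMax = 500L) {
  new("DesignGeometry", mode = "RELAXED_LEFT", label = "Relaxed-left",
      anchor = "right",
      distMin = as.integer(distMin), distMax = as.integer(distMax),
      productMin = as.integer(productMin), productOpt = as.integer(productOpt),
      productMax = as.integer(productMax))
}

#' @rdname tasOptGeometry
#' @export
defaultGeometries <- function() {
  list(tasOptGeometry(), relaxedRightGeometry(), relaxedLeftGeometry())
}

#' Resolve a design geometry against a template window
#'
#' Translates a [DesignGeometry-class] into the concrete per-side 3'-end
#' distance windows and primer quality settings the engine enumerates.
#' Anchored sides receive the strict distance range; the relaxed side may
#' place its 3' end anywhere between 1 bp and the product cap from the
#' target. Returns NULL (with a message) when the window cannot host even
#' the minimal geometry for this mode, e.g. when the target sits too close
#' to a contig edge; the waterfall treats that as a design failure for the
#' mode.
#'
#' @param window a [TemplateWindow-class]
#' @param geometry a [DesignGeometry-class]
#' @param primerLenMin,primerLenMax allowed primer lengths (nt)
#' @param tmMin,tmOpt,tmMax melting temperature window (Celsius)
#' @param gcMin,gcMax allowed GC percent bounds
#' @param maxHomopolymer longest allowed single-base run (nt)
#' @return a [DesignSpec-class], or NULL when the window is too short
#' @export
buildDesignSpec <- function(window, geometry,
                            primerLenMin = 18L, primerLenMax = 27L,
                            tmMin = 55, tmOpt = 60, tmMax = 65,
                            gcMin = 20, gcMax = 80, maxHomopolymer = 5L) {
  stopifnot(is(window, "TemplateWindow"), is(geometry, "DesignGeometry"))
  free <- c(1L, geometry@productMax)
  anch <- c(geometry@distMin, geometry@distMax)
  left <- switch(geometry@anchor, both = anch, left = anch, right = free)
  right <- switch(geometry@anchor, both = anch, right = anch, left = free)

  t0 <- window@targetOffset
  w <- nchar(window@seq)
  needLeft <- left[1] + primerLenMin - 1L
  needRight <- right[1] + primerLenMin - 1L
  if (t0 < needLeft || (w - 1L - t0) < needRight) {
    message("window too short for ", geometry@label, " at ",
            window@variantId, "; mode skipped")
    return(NULL)
  }

  new("DesignSpec",
      mode = geometry@mode, label = geometry@label,
      leftDistMin = left[1], leftDistMax = left[2],
      rightDistMin = right[1], rightDistMax = right[2],
      productMin = geometry@productMin, productOpt = geometry@productOpt,
      productMax = geometry@productMax,
      primerLenMin = as.integer(primerLenMin),
      primerLenMax = as.integer(primerLenMax),
      tmMin = tmMin, tmOpt = tmOpt, tmMax = tmMax,
      gcMin = gcMin, gcMax = gcMax,
      maxHomopolymer = as.integer(maxHomopolymer),
      symmetric = geometry@anchor == "both")
}

#' Emit the machine-readable design-engine input record for one attempt
#'
#' Serializes a resolved [DesignSpec-class] plus its window as a
#' Boulder-IO-style key=value record (the conventional batch input format
#' of command-line primer design engines), for audit alongside the actual
#' design run. Positions are 0-based.
#'
#' @param window a [TemplateWindow-class]
#' @param spec a [DesignSpec-class]
#' @return character vector of `KEY=value` lines terminated by `=`
#' @export
engineInputRecord <- function(window, spec) {
  c(paste0("SEQUENCE_ID=", window@variantId, "_", spec@label),
    paste0("SEQUENCE_TEMPLATE=", window@seq),
    paste0("SEQUENCE_TARGET=", window@targetOffset, ",1"),
    paste0("PRIMER_PRODUCT_SIZE_RANGE=", spec@productMin, "-",
           spec@productMax),
    paste0("PRIMER_PRODUCT_OPT_SIZE=", spec@productOpt),
    paste0("PRIMER_MIN_SIZE=", spec@primerLenMin),
    paste0("PRIMER_MAX_SIZE=", spec@primerLenMax),
    paste0("PRIMER_MIN_TM=", spec@tmMin),
    paste0("PRIMER_OPT_TM=", spec@tmOpt),
    paste0("PRIMER_MAX_TM=", spec@tmMax),
    paste0("PRIMER_MIN_GC=", spec@gcMin),
    paste0("PRIMER_MAX_GC=", spec@gcMax),
    "=")
}

# Enumerate quality-passing primer candidates on one side of the target.
# side "left": plus-strand primers whose 3' end lies dist bp upstream of
# the target; side "right": minus-strand primers (returned 5'->3') whose
# 3' end lies dist bp downstream. All offsets are 0-based within the
# window. Returns a data.frame with window coordinates, sequence, Tm, and
# a quality penalty.
enumerateCandidates <- function(window, spec, side = c("left", "right")) {
  side <- match.arg(side)
  t0 <- window@targetOffset
  w <- nchar(window@seq)
  dmin <- if (side == "left") spec@leftDistMin else spec@rightDistMin
  dmax <- if (side == "left") spec@leftDistMax else spec@rightDistMax
  lens <- seq(spec@primerLenMin, spec@primerLenMax)
  grid <- expand.grid(d = seq(dmin, dmax), len = lens)
  if (side == "left") {
    end3 <- t0 - grid$d                     # 0-based 3' end position
    start <- end3 - grid$len + 1L
    keep <- start >= 0L & end3 >= 0L
    grid <- grid[keep, , drop = FALSE]
    start <- start[keep]; end3 <- end3[keep]
    if (nrow(grid) == 0L) return(NULL)
    seqs <- substring(window@seq, start + 1L, end3 + 1L)
    out <- data.frame(start = start, end = end3, len = grid$len,
                      dist = grid$d, seq = seqs)
  } else {
    end3 <- t0 + grid$d                     # 0-based 3' end (leftmost base)
    stop0 <- end3 + grid$len - 1L
    keep <- stop0 <= w - 1L
    grid <- grid[keep, , drop = FALSE]
    end3 <- end3[keep]; stop0 <- stop0[keep]
    if (nrow(grid) == 0L) return(NULL)
    seqs <- revComp(substring(window@seq, end3 + 1L, stop0 + 1L))
    out <- data.frame(start = end3, end = stop0, len = grid$len,
                      dist = grid$d, seq = seqs)
  }
  ok <- !grepl("[^ACGT]", out$seq)
  out <- out[ok, , drop = FALSE]
  if (nrow(out) == 0L) return(NULL)
  gc <- gcPercent(out$seq)
  run <- maxHomopolymerRun(out$seq)
  out <- out[gc >= spec@gcMin & gc <= spec@gcMax &
             run <= spec@maxHomopolymer, , drop = FALSE]
  if (nrow(out) == 0L) return(NULL)
  out$tm <- primerTm(out$seq)
  out <- out[!is.na(out$tm) & out$tm >= spec@tmMin & out$tm <= spec@tmMax, ,
             drop = FALSE]
  if (nrow(out) == 0L) return(NULL)
  out$penalty <- abs(out$tm - spec@tmOpt)
  out[order(out$penalty), , drop = FALSE]
}

#' Design the best primer pair for one window under one resolved spec
#'
#' Enumerates candidate primers on both sides of the target within the
#' spec's distance windows, filters them on composition (A/C/G/T only, GC
#' bounds, homopolymer cap) and nearest-neighbor Tm, then ranks all
#' product-size-compatible pairings by a penalty combining Tm deviation
#' from the optimum, Tm difference between mates, product-size deviation,
#' and (for the strict mode) asymmetric target placement. Returns the
#' best-ranked pair, or NULL when no pair satisfies the constraints.
#'
#' @param window a [TemplateWindow-class]
#' @param spec a [DesignSpec-class] from [buildDesignSpec()], or NULL
#' @param maxCandidates per-side candidate cap before pairing (best-first)
#' @return a [PrimerPair-class], or NULL when no viable pair exists
#' @export
designPair <- function(window, spec, maxCandidates = 60L) {
  if (is.null(spec)) return(NULL)
  stopifnot(is(window, "TemplateWindow"), is(spec, "DesignSpec"))
  left <- enumerateCandidates(window, spec, "left")
  right <- enumerateCandidates(window, spec, "right")
  if (is.null(left) || is.null(right)) return(NULL)
  left <- utils::head(left, maxCandidates)
  right <- utils::head(right, maxCandidates)

  # product length for (i, j): right end - left start + 1
  prod <- outer(right$end, left$start, "-") + 1L     # rows: right, cols: left
  sizeOk <- prod >= spec@productMin & prod <= spec@productMax
  if (!any(sizeOk)) return(NULL)
  pen <- outer(right$penalty, left$penalty, "+") +
    0.5 * abs(outer(right$tm, left$tm, "-")) +
    0.02 * abs(prod - spec@productOpt)
  if (spec@symmetric)
    pen <- pen + 0.05 * abs(outer(right$dist, left$dist, "-"))
  pen[!sizeOk] <- Inf
  best <- arrayInd(which.min(pen), dim(pen))
  ri <- best[1]; li <- best[2]

  fwd <- left[li, ]; rev <- right[ri, ]
  ampStart0 <- window@windowStart + fwd$start            # 0-based half-open
  ampEnd0 <- window@windowStart + rev$end + 1L
  new("PrimerPair",
      pairName = paste0(window@variantId, "_", spec@label),
      fwdName = paste0(window@variantId, "_", spec@label, "_F"),
      revName = paste0(window@variantId, "_", spec@label, "_R"),
      fwdSeq = fwd$seq, revSeq = rev$seq,
      fwdTm = fwd$tm, revTm = rev$tm,
      mode = spec@mode, chrom = window@chrom,
      targetPos = window@pos,
      predictedProduct = as.integer(ampEnd0 - ampStart0),
      ampliconStart = as.integer(ampStart0),
      ampliconEnd = as.integer(ampEnd0))
}

#' Iterative waterfall design across a target table
#'
#' Attempts the strict TAS-opt geometry for every site first; sites with
#' no viable strict pair fall through to Relaxed-right, and remaining
#' failures to Relaxed-left. Fallback is triggered only by design failure
#' (no viable pair); a designed pair later rejected for concerning
#' off-targets is reported as-is, not redesigned. Per-site errors are
#' caught and reported as failed outcomes so a batch never aborts.
#'
#' @param targets a data.frame with columns CHROM, POS, PROJ (e.g. from
#'   [readTargetTable()])
#' @param reference reference genome (`DNAStringSet`, `FaFile`, or FASTA
#'   path)
#' @param flank template window half-width in bp
#' @param geometries ordered list of [DesignGeometry-class] objects
#' @param ... passed to [buildDesignSpec()] (primer quality settings)
#' @return a list of [DesignOutcome-class], one per input site, in input
#'   order
#' @export
waterfallDesign <- function(targets, reference, flank = 500L,
                            geometries = defaultGeometries(), ...) {
  genome <- asGenome(reference)
  lapply(seq_len(nrow(targets)), function(i) {
    chrom <- targets$CHROM[i]
    pos <- targets$POS[i]
    proj <- targets$PROJ[i]
    vid <- makeVariantId(proj, chrom, pos)
    attempted <- character(0)
    pair <- NULL
    res <- try({
      window <- extractWindow(genome, chrom, pos, proj, flank)
      for (geom in geometries) {
        attempted <- c(attempted, geom@mode)
        spec <- suppressMessages(buildDesignSpec(window, geom, ...))
        pair <- designPair(window, spec)
        if (!is.null(pair)) break
      }
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      message("design failed for ", vid, ": ",
              conditionMessage(attr(res, "condition")))
      attempted <- vapply(geometries, function(g) g@mode, "")
      pair <- NULL
    }
    if (length(attempted) == 0L)
      attempted <- vapply(geometries, function(g) g@mode, "")
    new("DesignOutcome",
        chrom = as.character(chrom), pos = as.integer(pos),
        proj = as.character(proj), variantId = vid,
        pair = pair, attemptedModes = attempted,
        primer3Ok = !is.null(pair))
  })
}
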