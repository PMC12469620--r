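#' Run the full design-screen-evaluate pipeline
#'
#' End-to-end driver: parse (or accept) the target table, run the
#' iterative TAS-opt / Relaxed-right / Relaxed-left design waterfall,
#' screen every designed pair genome-wide with the mismatch-tolerant
#' in-silico PCR matcher (FR, FF, and RR pairings), filter hits on decoy
#' contigs and the score threshold, evaluate off-targets by normalized
#' alignment similarity to the on-target amplicon, and assemble the final
#' annotated report. When `outDir` is given, writes `report.tsv`,
#' `offtarget_details.tsv`, and the audit `products.fasta` and `hits.bed`.
#'
#' @param targets a target table data.frame (CHROM/POS/PROJ) or a CSV path
#' @param reference reference genome (`DNAStringSet`, `FaFile`, or FASTA
#'   path)
#' @param outDir optional output directory
#' @param flank template window half-width (bp)
#' @param geometries ordered list of [DesignGeometry-class]
#' @param matcher a [MatcherParams-class]
#' @param minScore hit score retention threshold (default 750)
#' @param hqThreshold HQ off-target classification boundary (default 0.80)
#' @param decoys decoy-contig name patterns (substrings)
#' @param verbose log per-stage counts with message()
#' @return (invisibly) a list with `report` (data.frame), `outcomes`,
#'   `assessments`, and `hits` (per-site filtered hit `GRanges`)
#' @export
runPipeline <- function(targets, reference, outDir = NULL, flank = 500L,
                        geometries = defaultGeometries(),
                        matcher = MatcherParams(),
                        minScore = 750L, hqThreshold = 0.80,
                        decoys = decoyPatterns(), verbose = TRUE) {
  if (is.character(targets)) targets <- readTargetTable(targets)
  if (!"variant_ID" %in% names(targets))
    targets$variant_ID <- makeVariantId(targets$PROJ, targets$CHROM,
                                        targets$POS)
  genome <- asGenome(reference)
  say <- function(...) if (verbose) message(...)

  say("designing primers for ", nrow(targets), " target site(s)")
  outcomes <- waterfallDesign(targets, genome, flank = flank,
                              geometries = geometries)
  designed <- Filter(function(o) o@primer3Ok, outcomes)
  say("designed ", length(designed), "/", length(outcomes), " pair(s)")

  assessments <- list()
  hitsList <- list()
  for (out in designed) {
    pair <- out@pair
    hits <- scanPrimerPair(pair, genome, matcher)
    kept <- filterLowScore(filterDecoys(hits, decoys), minScore)
    assessments[[out@variantId]] <- assessSite(pair, kept, genome,
                                               hqThreshold)
    hitsList[[out@variantId]] <- kept
  }
  nOff <- sum(vapply(assessments, function(a) nrow(offTargets(a)), 0L))
  nConc <- sum(vapply(assessments, isConcerning, NA))
  say("screened ", length(designed), " pair(s): ", nOff,
      " retained off-target(s), ", nConc, " concerning site(s)")

  report <- buildReport(targets, outcomes, assessments)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeReport(report, file.path(outDir, "report.tsv"))
    writeOffTargetDetails(assessments,
                          file.path(outDir, "offtarget_details.tsv"))
    allHits <- if (length(hitsList))
      suppressWarnings(do.call(c, unname(hitsList))) else emptyHitRanges()
    writeProductsFasta(allHits, file.path(outDir, "products.fasta"))
    writeHitsBed(allHits, file.path(outDir, "hits.bed"))
    say("wrote report and audit files to ", outDir)
  }
  invisible(list(report = report, outcomes = outcomes,
                 assessments = assessments, hits = hitsList))
}
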