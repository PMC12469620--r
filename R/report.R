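# Final report assembly: merge design outcomes and specificity
# assessments back onto the input table.

# Canonical report columns appended after the input columns. Booleans are
# serialized as True/False; amplicon coordinates are 0-based half-open so
# amplicon_length == amplicon_end - amplicon_start.
reportColumns <- function() {
  c("variant_ID", "Primer3", "ISPCR", "primer_name", "TAS-opt",
    "forward_primer_name", "forward_primer_sequence", "forward_primer_tm",
    "reverse_primer_name", "reverse_primer_sequence", "reverse_primer_tm",
    "amplicon_start", "amplicon_end", "amplicon_length",
    "primer_count", "concerning_off_targets")
}

pyBool <- function(x) ifelse(x, "True", "False")

#' Assemble the final annotated report table
#'
#' One row per input site (no site is ever dropped), carrying all original
#' input columns followed by the canonical annotation columns: variant_ID,
#' Primer3 and ISPCR booleans, primer pair and per-primer names, sequences
#' and melting temperatures, the predicted amplicon interval (0-based
#' half-open) and length, the primer count (1 + number of retained
#' off-targets), and the concerning-off-targets flag. Rows are sorted by
#' chromosome (natural order: 1..22, X, Y, M, then others) and position.
#' For sites where design failed, all primer fields are empty, Primer3 and
#' ISPCR are False, and no assessment is required; a designed site without
#' an assessment is a pipeline inconsistency and raises an error.
#'
#' @param targets input table from [readTargetTable()]
#' @param outcomes list of [DesignOutcome-class] from [waterfallDesign()]
#' @param assessments list of [SiteAssessment-class] keyed (named) by
#'   variant_ID
#' @return data.frame in final column order, sorted
#' @export
buildReport <- function(targets, outcomes, assessments) {
  byId <- stats::setNames(outcomes, vapply(outcomes, variantId, ""))
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    vid <- targets$variant_ID[i]
    out <- byId[[vid]]
    if (is.null(out))
      stop("no design outcome for ", vid)
    base <- targets[i, setdiff(names(targets), "variant_ID"), drop = FALSE]
    ann <- stats::setNames(as.list(rep("", length(reportColumns()))),
                           reportColumns())
    ann$variant_ID <- vid
    ann$Primer3 <- pyBool(out@primer3Ok)
    if (!out@primer3Ok) {
      ann$ISPCR <- pyBool(FALSE)
      ann$`TAS-opt` <- pyBool(FALSE)
      ann$primer_count <- ""
      ann$concerning_off_targets <- ""
    } else {
      pair <- out@pair
      a <- assessments[[vid]]
      if (is.null(a))
        stop("assessment missing for designed site ", vid)
      ann$ISPCR <- pyBool(a@ispcrOk)
      ann$primer_name <- pair@pairName
      ann$`TAS-opt` <- pyBool(pair@mode == "TAS_OPT")
      ann$forward_primer_name <- pair@fwdName
      ann$forward_primer_sequence <- pair@fwdSeq
      ann$forward_primer_tm <- sprintf("%.2f", pair@fwdTm)
      ann$reverse_primer_name <- pair@revName
      ann$reverse_primer_sequence <- pair@revSeq
      ann$reverse_primer_tm <- sprintf("%.2f", pair@revTm)
      ann$amplicon_start <- pair@ampliconStart
      ann$amplicon_end <- pair@ampliconEnd
      ann$amplicon_length <- pair@ampliconEnd - pair@ampliconStart
      ann$primer_count <- a@primerCount
      ann$concerning_off_targets <- pyBool(a@concerning)
    }
    cbind(base, as.data.frame(ann, check.names = FALSE),
          stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report <- report[order(chromRank(report$CHROM), as.integer(report$POS)), ,
                   drop = FALSE]
  rownames(report) <- NULL
  report
}

#' Write the final report as tab-delimited text
#'
#' @param report data.frame from [buildReport()]
#' @param path output file path
#' @return the path, invisibly
#' @export
writeReport <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the per-site off-target detail table
#'
#' One row per retained off-target across all assessed sites: hit
#' coordinates (0-based half-open), query pairing, score, per-primer
#' mismatch counts, both normalized match values, and the HQ/LQ class.
#'
#' @param assessments list of [SiteAssessment-class]
#' @param path output file path
#' @return the path, invisibly
#' @export
writeOffTargetDetails <- function(assessments, path) {
  rows <- lapply(assessments, function(a) {
    df <- offTargets(a)
    if (nrow(df) == 0L) return(NULL)
    cbind(variant_ID = variantId(a), df, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_ID = character(0), chrom = character(0),
               start = integer(0), end = integer(0), pairing = character(0),
               score = integer(0), nMismFwd = integer(0),
               nMismRev = integer(0), nmToTest = numeric(0),
               nmToGold = numeric(0), class = character(0))
  rownames(out) <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
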