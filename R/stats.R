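#' Mutant allelic fraction
#'
#' The fraction of reads supporting the variant allele at a site:
#' `alt / depth`. Vectorized over sites.
#'
#' @param alt non-negative integer count of variant-supporting reads
#' @param depth positive integer total read depth
#' @return numeric vector of fractions in [0, 1]
#' @export
#' @examples
#' mafEstimate(c(0, 50), c(100, 100))
mafEstimate <- function(alt, depth) {
  if (any(depth <= 0)) stop("depth must be positive")
  if (any(alt < 0) || any(alt > depth))
    stop("alt must satisfy 0 <= alt <= depth")
  alt / depth
}

#' Wilson score confidence interval for an allelic fraction
#'
#' The plain Wilson interval (no continuity correction) around
#' `alt / depth`, with the normal quantile computed from the requested
#' confidence level rather than hard-coded, so levels other than 95% are
#' supported. The interval always contains the point estimate and is
#' well-behaved at extreme counts: at `alt = 0` the lower bound is exactly
#' 0, and at `alt = depth` the upper bound is exactly 1.
#'
#' @param alt non-negative integer count(s) of variant-supporting reads
#' @param depth positive integer total read depth(s)
#' @param confidence confidence level in (0, 1)
#' @return data.frame with columns `maf`, `lower`, `upper`
#' @export
#' @examples
#' wilsonInterval(5, 10)
#' wilsonInterval(0, 100)   # lower bound exactly 0
wilsonInterval <- function(alt, depth, confidence = 0.95) {
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)")
  p <- mafEstimate(alt, depth)
  n <- depth
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  lower <- pmax(0, center - half)
  upper <- pmin(1, center + half)
  lower[alt == 0] <- 0
  upper[alt == depth] <- 1
  data.frame(maf = p, lower = lower, upper = upper)
}
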