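---
title: "Designing and screening TAS primer panels with ampliScreen"
author: "ampliScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and screening TAS primer panels with ampliScreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(ampliScreen))
```

## The problem

Targeted amplicon sequencing (TAS) quantifies variants — including
low-level somatic mosaicism — by PCR-amplifying each site of interest and
sequencing the amplicons deeply on a short-read platform. A panel of
hundreds to a thousand sites needs hundreds of primer pairs, and every
pair needs two things that are tedious to do by hand: a geometry that
actually places the target under the sequenced bases, and a specificity
review that asks where else in the genome the pair could amplify.

ampliScreen automates both. It takes a CSV of target sites (`CHROM`,
`POS`, `PROJ`), designs one lead primer pair per site with a waterfall of
TAS-tuned geometries, screens each pair genome-wide with a
mismatch-tolerant in-silico PCR matcher, evaluates every predicted
off-target amplicon by alignment similarity to the on-target amplicon,
and merges everything back onto the input table as a tab-delimited
report.

## Amplicon geometry for 150 bp paired-end reads

The strict geometry, *TAS-opt*, places both primer 3' ends 60–100 bp
from the target with an optimal product of 190 bp (allowed range
150–200 bp). With 150 bp paired-end reads, both mates of a ~190 bp
fragment then cover the target base, doubling the usable depth at the
site. The two fallback geometries trade that redundancy for yield:
*Relaxed-right* keeps the forward primer anchored at 60–100 bp but lets
the reverse primer sit anywhere compatible with a product of at most
500 bp; *Relaxed-left* mirrors it. The target is then covered by one
read end instead of two.

Design runs as an iterative waterfall: TAS-opt is attempted for every
site; only sites with no viable strict pair are retried as
Relaxed-right, and only remaining failures as Relaxed-left. Fallback is
triggered by design failure alone — a designed pair that is later
rejected for concerning off-targets is reported as such, not silently
redesigned, so the user sees the specificity problem.

```{r geometry}
tasOptGeometry()
relaxedRightGeometry()
```

### The built-in design engine

Candidate primers (18–27 nt) are enumerated at every allowed 3'-end
position, filtered on composition (A/C/G/T only — candidates overlapping
N are excluded — GC between 20 and 80%, homopolymer runs of at most 5),
and on melting temperature between 55 and 65 °C computed from unified
nearest-neighbor thermodynamics (50 nM oligo, 50 mM Na+). Surviving
candidates are ranked by a penalty combining Tm deviation from 60 °C,
the Tm difference between mates, product-size deviation from the
optimum, and, for TAS-opt, asymmetric placement of the target between
the two 3' ends. The single best-ranked pair per site is retained; on
request, `engineInputRecord()` emits the Boulder-IO-style settings
record of each attempt for audit. All of these quality settings are
engine defaults and can be overridden through `buildDesignSpec()`; only
the geometry settings differ between modes.

## In-silico PCR screening

Specificity is screened with a seed-and-extend matcher whose defaults
mirror mismatch-tolerant in-silico PCR screening: an exact 11-mer tile
of the primer, sampled every 5 bases, must hit a locus
(`tileSize`/`stepSize`); the 3'-terminal base must match exactly
(`minPerfect = 1`); and within the 3'-most 15 bases there must be at
least two matches per mismatch (`minGood = 15`). Binding is gapless — no
indels are modeled, a documented approximation that matches the dominant
behavior of tile-based matching at these settings. Convergent binding
pairs on one contig with an outer span of at most `maxSize = 800` bp
become candidate products; products never span contigs.

Because a single primer can prime both strands, each pair is screened as
three query pairings: forward/reverse (FR, in both orientations),
forward/forward (FF), and reverse/reverse (RR).

Each hit receives a 0–1000 viability score. A mismatch-free hit scores
exactly 1000. The penalty scheme is this package's documented
convention (the published anchor points are the perfect score of 1000
and the downstream retention threshold of 750): each primer contributes
a weight `w = sum(2 if the mismatch lies in the 3'-most 5 bases else
1) / primer length`, and the score is `round(1000 * (1 - (wF + wR)/2))`
clipped to [0, 1000], so 3'-proximal mismatches — which compromise
extension most — are penalized twice as heavily.

```{r scan}
fix <- simulateGenome(c(chr1 = 50000L), seed = 11)
targets <- data.frame(CHROM = "chr1", POS = 25000L, PROJ = "demo")
outcome <- waterfallDesign(targets, fix)[[1]]
primerPair(outcome)
hits <- scanPrimerPair(primerPair(outcome), fix)
hits$score
```

## Off-target evaluation

Hits on decoy contigs (names containing `_alt`, `_random`, `_decoy`,
`chrUn`, `_fix`, or `HLA-`; configurable) are removed first, then hits
scoring below 750 are dropped — a hit at exactly 750 is retained, per
the strict less-than reading of the cut. Every remaining off-target
product is aligned globally to the on-target amplicon with match +1,
mismatch 0 and no gap costs, so the score is the size of the best
co-linear match set and normalized values live in [0, 1]. The score is
normalized twice — by the off-target length (`toTest`) and by the
on-target length (`toGold`) — so partial and oversized products are both
measured sensibly.

An off-target reaching 80% normalized match is a high-quality,
*concerning* off-target (HQ); below 80% it is low-quality (LQ). The
boundary is inclusive (exactly 80% is HQ), and the driving statistic is
the larger of the two normalized values — the conservative,
more-flagging choice, made here because the two denominators are
otherwise equally defensible. Both values are recorded per off-target in
the detail table so users can re-threshold. The summary per site is
`primer count` (1 + number of retained off-targets, so 1 means a clean
pair) and the boolean `concerning off-targets` (any HQ call). When every
hit — including the on-target — is filtered away, `ISPCR` is False and
off-targets are still evaluated against the design-predicted amplicon
slice so the report stays complete.

```{r evaluate}
pair <- primerPair(outcome)
dup <- plantOffTarget(fix, "chr1", pair@ampliconStart + 1L,
                      pair@ampliconEnd, "chr1", 5000L, divergence = 0)
assessment <- assessSite(pair, scanPrimerPair(pair, dup$genome),
                         dup$genome)
assessment
offTargets(assessment)[, c("start", "end", "score", "nmToTest", "class")]
```

## The synthetic-fixture generator

Everything above is exercised on simulated miniature references:
contigs of i.i.d. uniform A/C/G/T at a fixed seed (`simulateGenome()`),
target tables drawn with a safety margin from contig ends
(`simulateTargets()`), and planted off-target copies of realized
amplicons at an exact substitution divergence (`plantOffTarget()`).
Planting can preserve the primer footprints while diverging the
interior, which decouples "will it amplify" (binding survival) from
"does it look like the target" (amplicon similarity); a `primerOnly`
mode plants just the two footprints at the correct spacing. Divergence
is substitution-only because the matcher models no indels.

Uniform background at the 10 kb–2 Mb scales used here keeps 11-mers
near-unique, so fixtures are designable and off-target-free except where
copies are planted — which is exactly what makes planted-copy tests
interpretable. Real genomes are not like this: repeats, segmental
duplications, GC skew, and N-gaps all make design harder and off-targets
more common. Passing fixture tests therefore validates the machinery
(coordinates, rules, thresholds, determinism), not expected panel yield
on a real reference.

At the default planted divergence used in the LQ scenarios (40%
substitutions over a ~190 bp amplicon), the normalized match falls well
below the 0.80 boundary, while an exact copy scores 1.0:

```{r divergence}
gold <- as.character(Biostrings::subseq(fix[["chr1"]],
                                        pair@ampliconStart + 1L,
                                        pair@ampliconEnd))
div <- plantOffTarget(fix, "chr1", pair@ampliconStart + 1L,
                      pair@ampliconEnd, "chr1", 5000L, divergence = 0.40,
                      preservePrimerSites = TRUE,
                      fwdLen = nchar(pair@fwdSeq),
                      revLen = nchar(pair@revSeq), seed = 2)
offSeq <- as.character(Biostrings::subseq(div$genome[["chr1"]],
                                          div$destStart, div$destEnd))
normalizedMatch(offSeq, gold)
```

## Allele-fraction statistics

For downstream TAS analysis the package provides the mutant allelic
fraction (`alt / depth`) and its Wilson score interval.
`wilsonInterval()` uses the plain Wilson form without continuity
correction, computes the normal quantile from the requested confidence
level rather than hard-coding 1.96, and is exact at the boundaries: the
lower bound at `alt = 0` is 0 and the upper bound at `alt = depth` is 1.

```{r wilson}
wilsonInterval(c(0, 5, 50), c(100, 10, 100))
```

## Numerical and interface choices

* **Coordinates.** `POS` is 1-based (VCF/ClinVar convention); all
  internal arithmetic is 0-based half-open; BED output, FASTA headers,
  and the report's amplicon columns are 0-based half-open, so
  `amplicon_length = amplicon_end - amplicon_start`.
* **Naming.** The pair is `<variant_ID>_<mode-label>` with mode labels
  exactly `TAS-opt`, `Relaxed-right`, `Relaxed-left`; primers carry `_F`
  and `_R` suffixes. `variant_ID` is `PROJ_CHROM_POS`.
* **Sorting.** The report sorts by chromosome then position, with
  natural chromosome order (1..22, then X, Y, M, then other contigs
  lexicographically) since the name set alone defines no total order.
* **Duplicates.** Input rows duplicating (CHROM, POS, PROJ) would
  collide on `variant_ID` and are collapsed to one with a warning.
* **On-target assignment.** The on-target hit must overlap the target
  position and come from the FR pairing; ties break by higher score,
  then smaller product. FF/RR hits are never flagged on-target.
* **Determinism.** All randomness (fixtures only) flows through explicit
  seeds; a fixed seed reproduces the final report byte for byte.
* **Problem sizes.** The test and demonstration fixtures use 8–50 kb
  contigs and one to six sites, where exhaustive brute-force oracles
  (all-offset matching, LCS dynamic programming) remain cheap enough to
  cross-check every engine decision; the engines themselves have no
  intrinsic size limit beyond memory.

## Known limitations

The design engine optimizes geometry and basic primer quality but does
not model hairpins, primer dimers, or cross-pair interactions in a
multiplexed panel; it adds no adapter tails and is unaware of gene or
exon boundaries, so it suits genomic DNA amplification. The matcher has
no thermodynamic (free-energy) binding model and no indel tolerance. No
attempt is made to predict sequencing coverage; the HQ/LQ call is an
in-silico similarity statement, not a wet-lab guarantee.
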