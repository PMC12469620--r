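# ampliScreen

Batch PCR primer design with genome-wide specificity screening, tuned
for targeted amplicon sequencing (TAS) panels on 150 bp paired-end
platforms.

## What it does and for whom

Researchers running TAS panels — deep sequencing of PCR amplicons to
quantify variants, down to low-level mosaicism — need one primer pair
per target site, for hundreds of sites at a time, and each pair needs a
specificity review: where else in the genome could it amplify, and do
those off-target products look enough like the real amplicon to corrupt
the analysis? ampliScreen automates the whole loop:

1. **Design.** For each row of a `CHROM,POS,PROJ` table, design a pair
   with the strict *TAS-opt* geometry: both primer 3' ends 60–100 bp
   from the target, product optimized at 190 bp, so both mates of a
   150 bp paired-end read cover the target. Sites that fail fall
   through a waterfall to *Relaxed-right*, then *Relaxed-left*, which
   anchor one primer and allow products up to 500 bp.
2. **Screen.** A mismatch-tolerant seed-and-extend in-silico PCR
   matcher (exact 11-mer seeds every 5 bases, exact 3'-terminal base,
   ≥2 matches per mismatch in the 3'-most 15 bases, products ≤800 bp)
   finds every convergent binding configuration genome-wide, for the
   FR, FF, and RR query pairings, and scores each hit 0–1000; a
   mismatch-free hit scores exactly 1000.
3. **Evaluate.** After removing decoy-contig hits and hits scoring
   below 750, every off-target product is globally aligned to the
   on-target amplicon (match +1, mismatch 0, no gap cost) and
   normalized by both amplicon lengths. An off-target at ≥80%
   normalized match is a high-quality, *concerning* off-target (HQ);
   below that, low-quality (LQ). The report records, per site, the
   primer count (1 + off-targets) and a concerning flag.

Deterministic synthetic fixtures (seeded miniature genomes with planted
off-target copies at exact divergence) make every stage testable with
no downloads, and `mafEstimate()` / `wilsonInterval()` cover the
downstream allele-fraction statistics.

## Worked example

```r
library(ampliScreen)

genome  <- simulateGenome(c(chr1 = 50000L), seed = 11)
targets <- data.frame(CHROM = "chr1", POS = 25000L, PROJ = "demo")
res <- runPipeline(targets, genome)
#> designing primers for 1 target site(s)
#> designed 1/1 pair(s)
#> screened 1 pair(s): 0 retained off-target(s), 0 concerning site(s)

res$report[, c("variant_ID", "primer_name", "amplicon_length",
               "primer_count", "concerning_off_targets")]
#>        variant_ID             primer_name amplicon_length primer_count concerning_off_targets
#> 1 demo_chr1_25000 demo_chr1_25000_TAS-opt             184            1                  False
```

A primer count of 1 means the pair amplifies exactly one locus. Plant
an exact copy of the realized amplicon elsewhere and the screen finds
it, the count becomes 2, and the site is flagged, since a perfect copy
is a 100% (HQ) off-target:

```r
pair <- primerPair(res$outcomes[[1]])
dup  <- plantOffTarget(genome, "chr1", pair@ampliconStart + 1L,
                       pair@ampliconEnd, "chr1", 5000L, divergence = 0)
res2 <- runPipeline(targets, dup$genome, verbose = FALSE)
res2$report[, c("variant_ID", "primer_count", "concerning_off_targets")]
#>        variant_ID primer_count concerning_off_targets
#> 1 demo_chr1_25000            2                   True

offTargets(res2$assessments[[1]])
#>   chrom start  end pairing score nMismFwd nMismRev nmToTest nmToGold class
#> 1  chr1  4999 5183      FR  1000        0        0        1        1    HQ
```

The off-target detail table gives coordinates (0-based half-open), the
hit score, per-primer mismatch counts, both normalized match values,
and the HQ/LQ class. For sequencing results, the Wilson interval around
a mutant allelic fraction of 3/2000 reads:

```r
wilsonInterval(3, 2000)
#>      maf        lower       upper
#> 1 0.0015 0.0005102636 0.004401033
```

A command-line wrapper over the same functions lives at
`inst/scripts/ampliscreen.R` (`run` for the pipeline, `maf` for the
statistics); `runPipeline(..., outDir = )` writes `report.tsv`, an
off-target detail table, and audit `products.fasta` / `hits.bed`.

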