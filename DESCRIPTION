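Package: ampliScreen
Title: Batch Primer Design and In-Silico PCR Specificity Screening for
    Targeted Amplicon Sequencing Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs PCR primer pairs for large tables of genomic target
    sites, screens each pair genome-wide with a mismatch-tolerant in-silico
    PCR engine (including same-orientation forward-forward and
    reverse-reverse pairings), and evaluates every predicted off-target
    amplicon by normalized alignment similarity to the on-target amplicon.
    Primer geometry is optimized for targeted amplicon sequencing on a
    150 bp paired-end platform: an ideal ~190 bp amplicon with both primer
    3' ends 60-100 bp from the target, with relaxed one-sided fallback
    geometries up to 500 bp applied iteratively for sites that fail strict
    design. Includes deterministic synthetic-genome fixtures with planted
    off-target copies at controlled divergence, allele-fraction statistics
    with Wilson confidence intervals, and a tab-delimited report writer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, SequenceMatching, Software
RoxygenNote: 7.3.3
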