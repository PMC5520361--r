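Package: ssrpipe
Title: Microsatellite Marker Development and Diversity Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines perfect simple sequence repeats (SSRs) from assembled
    contigs, selects marker-grade loci by coverage, contig-length and
    locus-independence filters, designs multiplex-ready primer pairs with
    expected product sizes, and computes the descriptive and diversity
    statistics used in codominant-marker studies: observed and unbiased
    expected heterozygosity, polymorphic information content (PIC),
    Tandem-style allele binning, cross-species transferability summaries,
    Band-coefficient (Dice) genetic distances with principal coordinate
    analysis, Evanno delta-K model selection and Q-threshold cluster
    assignment. A seeded synthetic-data module generates contigs with
    planted repeat tracts, Hardy-Weinberg genotypes, transfer matrices and
    ln P(D) replicate series with known ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
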