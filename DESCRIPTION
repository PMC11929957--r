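Package: mitohet
Title: Split-Read Detection and Heteroplasmy Quantification of Mitochondrial Deletions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects deletions at direct-repeat loci of the circular human
    mitochondrial genome from split sequencing reads and quantifies their
    heteroplasmy against a local-depth benchmark. Provides circular-coordinate
    reference handling with left-alignment of breakpoints that are ambiguous
    inside tandem repeats, a targeted single-gap split-read aligner, SAM/BAM
    ingestion of pre-mapped alignments, local-depth normalised heteroplasmy
    estimation with Wilson confidence intervals, haplogroup-stratified cohort
    summaries with exact nonparametric tests, and a seeded synthetic-read
    generator emulating present-day deep coverage and ancient low-coverage
    libraries so the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    emmeans,
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    VariantAnnotation,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
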