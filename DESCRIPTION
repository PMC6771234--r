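Package: cistrio
Title: Combinatorial Cistrome Integration for Multi-Factor ChIP-Seq Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates multiple transcription-factor cistromes around an
    anchor factor: overlap-coefficient screening of candidate cofactors,
    binned read-density quantification in reads per 10 million mapped reads
    per 100 bp, combinatorial co-binding classification by binary site codes,
    stitch-and-rank super-enhancer identification with a tangent-slope
    cutoff, weaker/unchanged/stronger classification of binding change after
    a knockdown, and Kaplan-Meier survival stratification of patients by
    binary expression codes. Ships a seeded synthetic-cistrome generator so
    every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
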