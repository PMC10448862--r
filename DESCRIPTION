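Package: linkphase
Title: Linked-Read Structural Variant Discovery, Barcode Phasing and
    Copy-Number Analysis of Amplified Oncogene Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing barcode-linked (droplet-partitioned)
    short-read DNA sequencing of structurally complex, highly amplified
    oncogene loci such as the androgen receptor (AR) locus in
    castration-resistant prostate cancer. Reconstructs high-molecular-weight
    DNA molecules from barcoded alignments at configurable gap parameters,
    seeds structural-variant candidates from discordant read pairs, scores
    them by barcoded split-molecule support, merges calls across gap
    parameters, phases structural variants into networks through shared
    barcodes, estimates targeted copy number from depth ratios, filters
    oncogenic single-nucleotide variants, and aggregates per-sample calls
    into cohort-level Fisher's exact enrichment tests. Includes a
    linked-read simulator of multiply-rearranged, optionally circular
    (ecDNA-like) derivative amplicons with machine-readable truth so the
    whole pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    Rsamtools,
    vcfR,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
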