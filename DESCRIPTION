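Package: resilencer
Title: Single-Molecule and Bulk Epigenetic Analysis of Gene Resilencing
    Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracking the resilencing of a drug-reactivated,
    promoter-hypermethylated gene after withdrawal of a hypomethylating
    agent. Implements context-aware (WCG/GCH) methylation and accessibility
    calling from bisulfite-converted clone sequences, nucleosome footprint
    detection from GpC methyltransferase accessibility (NOMe-seq),
    single-molecule classification into demethylated and hypermethylated
    promoter states, delta-delta-Ct relative expression, MNase-qPCR relative
    nucleosome levels, ChIP-qPCR enrichment, pyrosequencing averaging,
    LC-MS/MS global methylation percentages, and event-ordering statistics
    (half-recovery days) for the resulting time courses. A fully
    ground-truthed simulator emulates promoter molecule populations,
    M.CviPI treatment, bisulfite conversion, biased amplification and qPCR
    runs so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
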