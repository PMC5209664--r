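Package: epimutools
Title: Calling and Tracking DNA Methylation Epimutations Across Generations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for whole-genome bisulfite sequencing methylome
    analysis in multi-generation stress-exposure designs. Calls methylated
    cytosines with binomial tests calibrated on an unmethylated lambda
    spike-in, identifies differentially methylated positions (DMPs),
    single-cytosine methylation polymorphisms (SMPs) and sliding-window
    differentially methylated regions (DMRs), and quantifies recurrence
    ("hot spots"), maintenance and transgenerational inheritance of
    epimutations across generations. Includes a synthetic methylome
    generator with planted, heritable epimutations and a truth ledger so
    every stage can be validated without external sequencing data, plus
    genomic-context annotation and metagene profiling utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
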