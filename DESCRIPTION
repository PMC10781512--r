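Package: miredit
Title: Detection and Differential Analysis of A-to-I MicroRNA Editing
    from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for calling adenosine-to-inosine
    (A-to-I) editing sites in mature microRNAs from small RNA sequencing
    reads aligned to hairpin precursors.  Includes a bounded-mismatch
    ungapped read aligner with per-position base tallies, a binomial
    sequencing-error filter for site calling, Welch t-tests with
    Benjamini-Hochberg correction for differential editing between two
    groups, abundance-correlation residual diagnostics, canonical seed
    match (8mer, 7mer-m8, 7mer-A1) target-pool comparison between edited
    and non-edited isomiRs, trinucleotide editing-context tables, and a
    fully seeded synthetic small RNA-seq read generator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringi,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
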