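Package: ampliphase
Title: Minor Variant Calling, Clonal Phasing and Isoform Detection for
    Long-Read Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-molecule long-read (circular consensus)
    amplicon sequencing of fusion transcripts such as BCR-ABL1 p210.
    Models the fusion-transcript reference and its PCR amplicon, aligns
    full-length consensus reads with a banded affine-gap semi-global
    aligner, calls minor point variants down to sub-percent frequencies
    against a sequencing-error floor, phases mutations per molecule to
    separate compound from independent clones, detects splice isoforms
    from full-length reads, and quantifies assay sensitivity on simulated
    serial dilution series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
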