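Package: spliceland
Title: Alternative Splicing Landscape Analysis from Transcript Models and
    Junction Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising an alternative-splicing landscape from
    assembled transcript models and per-sample splice-junction support tables.
    Detects the five local event types (skipped exon, retained intron,
    alternative 5'/3' splice site, mutually exclusive exons) by pairwise
    isoform comparison, applies read-support filters to splice junctions,
    computes intron sequence features (length, AU-richness, border
    dinucleotides, position-weight-matrix splice-site scores), quantifies
    events with percent-spliced-in (PSI) and the AS score, calls tissue- and
    stage-specific events with the Tau index, and tests differential
    splicing with a binomial likelihood-ratio test under
    Benjamini-Hochberg FDR control. Includes a synthetic-data generator
    that plants events, border composition and per-tissue PSI structure
    with a ground-truth manifest, so every stage can be validated.
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
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
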