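Package: hypertx
Title: Spike-In Calibrated Analysis of Global Transcription Output and
    Protein-DNA Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for detecting and characterising
    hypertranscription, a global increase in RNA synthesis that is invisible
    to normalisations assuming equal totals. Implements spike-in anchored
    size factors with negative-binomial Wald differential expression,
    dominant transcription start site refinement from nascent run-on 3'-end
    signal (PRO-seq), intergenic-background calibration of ChIP-seq coverage
    with expression-quantile gene classes, worm-like-chain analysis of
    magnetic-tweezer force scans (compaction ratio and hysteresis), and
    hydrogen-bond occupancy filtering over molecular-dynamics trajectory
    frames. Every stage is paired with a seeded synthetic-data generator
    that emulates the statistical structure the analysis assumes, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
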