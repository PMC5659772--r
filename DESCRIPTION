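Package: maccr
Title: Chromatin Accessibility Scoring from MNase Titration Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies chromatin accessibility from micrococcal nuclease
    (MNase) digestion series sequenced at several enzyme concentrations.
    Mapped fragments are counted in fixed-width genomic bins, library-size
    normalized, and the per-bin slope of read frequency against negative
    log concentration yields an accessibility score (the MACC statistic),
    optionally corrected for GC-content bias by local regression. The
    package also provides differential accessibility between RNAi
    conditions using a moderated two-sample t statistic, site-anchored
    average profiles and metagene heatmaps, nascent-transcription (Start-seq)
    regulation summaries, ChIP-qPCR percent-input enrichment math, and a
    seeded synthetic-data generator with known ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
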