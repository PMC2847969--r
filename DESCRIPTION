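Package: ucetx
Title: Strand-Specific Transcription Analysis of Ultraconserved Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline for studying transcription of
    ultraconserved elements (UCEs) during development. Provides
    strand-specific expression calling from custom tiling-microarray probe
    intensities (quantile normalization, 90th-percentile and
    negative-control thresholds, replicate agreement), classification of
    constitutively expressed elements by maximal fold change and
    coefficient of variation, genomic-context classification and
    Fisher/Hochberg enrichment, matched random background-region sampling
    with annotation filters, RNA-Seq coverage quantification with an
    empirical resampling Z test, flanking-transcription analysis, and
    cross-dataset integration with enhancer-assay and human expression
    call sets. A synthetic-data generator with planted ground truth
    emulates every input so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    limma,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
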