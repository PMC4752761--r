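Package: isobind
Title: Integrate ChIP-Seq Binding and Differential Expression to Call
    Isoform-Specific Direct Target Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating transcription-regulator ChIP-seq peak
    sets with differential-expression tables to classify direct target
    genes, designed around two-isoform comparisons such as the Drosophila
    SIN3 187/220 system. Provides input-enrichment peak filtering,
    replicate-concordance filtering, reciprocal peak-set overlap reports,
    strand-aware peak-to-gene assignment, chromosomal-distribution
    binomial enrichment, eight-category genomic-feature annotation,
    gene-body-scaled metagene signal profiles, direct-target calling
    under knockdown and overexpression contrasts, a four-class (A/B/C/D)
    regulatory partition, hypergeometric and EASE-style term enrichment
    with category pooling, ChIP-qPCR percent-of-input and RT-qPCR
    delta-delta-Ct quantification, and a synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
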