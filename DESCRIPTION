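Package: oxoprofiler
Title: Genome-Wide 8-Oxoguanine ChIP-Seq Damage Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies genome-wide oxidative DNA damage from anti-8-oxoguanine
    ChIP-seq alignments. Reads are filtered on mapping quality and
    mitochondrial origin, binned by first-base position into fixed-width
    genomic windows, normalized to the filtered library size, sparse bins are
    discarded, and per-chromosome totals are averaged across replicate
    experiments and compared between conditions with an exact paired Wilcoxon
    signed-rank test. Also provides the 6-thioguanine (HPRT) induced
    mutant-frequency metric for colony assays, and a synthetic aligned-read
    simulator that emulates two-condition replicate ChIP datasets for
    calibration and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    BiocGenerics,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
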