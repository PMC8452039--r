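Package: sdrscan
Title: Coverage-Based Detection of Sex-Determination Regions with
    Assembly and Methylation Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects male-specific (sex-determination) regions in an XY
    system from male/female resequencing depth: fixed-window coverage,
    per-window Welch tests with Benjamini-Hochberg correction, run-merging
    into candidate regions and 1-kb boundary refinement with per-part
    regression, plus marker intersection. Also computes assembly
    contiguity statistics (N50/L50, gaps, GC), telomere-repeat detection
    at contig ends, CpG methylation-frequency summarisation with a
    read-support filter, methylation-dependent restriction-enzyme
    (FspEI/MspJI) site models with cross-platform overlap, and a per-site
    differential-methylation screen. Ships a synthetic-data generator
    emulating hemizygous depth signatures and bimodal CpG methylation so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
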