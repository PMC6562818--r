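Package: poolvar
Title: Pooled Capture-Sequencing Variant Discovery and Group Comparison
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Variant discovery and comparison pipeline for pooled
    (pool-seq) targeted capture sequencing of divergent lines. Calls SNPs
    and indels per pool from samtools-style text pileups using a binomial
    error model with Benjamini-Hochberg false-discovery-rate control,
    annotates variants against gene models (proximal promoter, UTR, CDS,
    intron, with codon-level synonymous/non-synonymous effect calls and
    multi-gene assignment for overlapping genes), partitions variants into
    breed-specific, group-specific, shared and same-position
    different-allele sets across a two-breed by two-phenotype-group
    design, and emits the standard summary report tables. A synthetic-data
    module generates genomes, gene models, planted truth variants and
    noisy pool pileups so the whole pipeline can be exercised and
    validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
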