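Package: ogmap
Title: Genome-Wide Mapping of 8-Oxoguanine Enrichment from OG-Seq Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for affinity-pulldown sequencing of the
    oxidative DNA lesion 8-oxoguanine (OG-seq). Implements signal
    extraction scaling (SES) normalization of pulldown against input,
    percentile-based calling of OG-enriched 1 kb bins with technical and
    biological replicate consensus, negative-binomial differential
    enrichment of OG over genomic features and G-quadruplex windows,
    canonical G4 motif scanning, differential expression of matched RNA
    counts, and promoter-level concordance clustering of OG damage with
    gene expression. Includes a synthetic-data generator with known
    ground truth that emulates a four-genotype glycosylase-knockout
    study design, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, Epigenetics, Coverage, DifferentialExpression
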