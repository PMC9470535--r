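Package: scvarmap
Title: Single-Cell Somatic Variant Mapping and Tumor Program Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing somatic mutations and copy-number events to
    individual cells in barcoded single-cell RNA-seq data. Implements
    consensus filtering of multi-caller somatic and germline variant call
    sets, hotspot variant-allele-fraction genotyping, UMI-aware per-cell
    allele counting with majority-consensus deduplication, a continuity
    corrected two-proportion Z statistic for preferential mutation mapping
    with a one-sided skip rule and FDR control, cell quality-control
    filtering, Wilcoxon rank-sum differential expression, hypergeometric
    gene-set over-representation, tumor-subcluster pathway scoring,
    spatially-distinct-cluster assignment, upper-quartile FPKM
    normalization, and arm-level summarization of gene-level copy-number
    matrices. Includes a fully seeded synthetic-cohort generator with
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    withr,
    vcfR,
    fgsea,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
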