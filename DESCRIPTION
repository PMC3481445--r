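Package: ccnvtools
Title: Comparative Copy-Number Variant Merging and Concordance Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Merges copy-number variant (CNV) call sets produced by multiple
    read-depth caller configurations into comparative CNV (cCNV) regions:
    granular genomic segments carrying one copy-number value per
    configuration. Provides base-pair Jaccard concordance between
    configurations stratified by genic, non-genic and validated-CNV
    annotation, copy-number bin profiles with fraction-change statistics, an
    exact Wilcoxon rank-sum test for stratified comparisons, readers for
    common caller output dialects (BED4, FREEC-style, CNV-seq-style), and a
    synthetic call-set generator with controllable shared-truth structure,
    boundary jitter, false calls and configuration-specific deletion
    suppression for end-to-end benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: CopyNumberVariation, Coverage, Normalization, StructuralVariation
RoxygenNote: 7.3.3
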