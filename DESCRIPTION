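Package: myomultiome
Title: Paired Single-Cell RNA and ATAC Analysis of Embryonic Myogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint analysis of single-cell RNA-seq and
    single-cell ATAC-seq data along a myogenic differentiation trajectory:
    per-cell quality control for both modalities (UMI/gene/mitochondrial
    filters; fragment counts, TSS enrichment, nucleosome signal, FRiP),
    priority-based stratification of open-chromatin peaks into genomic
    element classes, differential expression (Wilcoxon rank-sum) and
    differential accessibility (Fisher exact and logistic regression with a
    fragment-count covariate), gene activity scoring from peak fragment
    counts, motif enrichment z-scores for cell-type-specific peak sets,
    cis-regulatory peak-to-gene linking, cross-modality correlation of
    cell-type assignments, and pseudotime gene-trend clustering. Includes a
    synthetic paired-multiome generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    rtracklayer,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
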