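#!/usr/bin/env Rscript
# Step 2 — per-cell quality control for both modalities.
#
# RNA cells are dropped below 200 detected genes, above 30,000 UMIs, above
# 10% mitochondrial counts or when flagged as doublets (> 40,000
# transcripts); genes detected in fewer than 3 surviving cells are dropped.
# ATAC barcodes are kept with 2,000-30,000 fragments, mitochondrial ratio
# < 2%, TSS enrichment in (2, 40), nucleosome signal < 5 and FRiP > 50%.

suppressPackageStartupMessages(library(myomultiome))

rna <- read_mtx_dir("results/data/rna")
atac <- read_mtx_dir("results/data/atac")
peaks <- read_peaks_bed("results/data/peaks.bed")
ann <- read_annotation_gtf("results/data/annotation.gtf")
frags <- read_fragments("results/data/fragments.tsv")

mito_genes <- grep("^MT-", rownames(rna), value = TRUE)
rna_qc <- compute_rna_qc(rna, mito_genes)
rna_f <- filter_rna(rna, rna_qc)

atac_qc <- compute_atac_qc(frags, peaks, ann, barcodes = colnames(atac))
atac_f <- filter_atac(atac, atac_qc)

dir.create("results", showWarnings = FALSE)
write.table(rna_qc, "results/rna_qc.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(atac_qc, "results/atac_qc.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write_mtx_dir(rna_f$matrix, "results/data/rna_filtered")
write_mtx_dir(atac_f$matrix, "results/data/atac_filtered")

cat("RNA: ", ncol(rna), "cells ->", ncol(rna_f$matrix), "kept;",
    "genes:", nrow(rna), "->", nrow(rna_f$matrix), "\n")
print(rna_f$report)
cat("ATAC:", ncol(atac), "cells ->", ncol(atac_f$matrix), "kept\n")
print(atac_f$report)
cat("median TSS enrichment:",
    round(median(atac_qc$tss_enrichment), 2),
    " median nucleosome signal:",
    round(median(atac_qc$nucleosome_signal), 2),
    " median FRiP:", round(median(atac_qc$frip), 3), "\n")
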