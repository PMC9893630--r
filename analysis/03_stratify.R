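#!/usr/bin/env Rscript
# Step 3 — genomic element stratification of the open chromatin landscape.
#
# Peaks detected in more than 10% of the cells of interest are classified by
# the priority rule exon > promoter > 5'-UTR > 3'-UTR > intron > distal,
# overall and per cell type. Also computes the shared/unique accessible-peak
# accounting across types and the [0,1]-standardized per-type accessibility
# of the strongest marker genes (gene body +/- 2 kb windows).

suppressPackageStartupMessages(library(myomultiome))

atac <- read_mtx_dir("results/data/atac_filtered")
peaks <- read_peaks_bed("results/data/peaks.bed")
ann <- read_annotation_gtf("results/data/annotation.gtf")
cells <- read.delim("results/data/cells.tsv")
cells <- cells[match(colnames(atac), cells$barcode), ]

strat_all <- stratify_peaks(peaks, ann, atac, colnames(atac))
per_type <- sapply(unique(cells$cell_type), function(t)
  stratify_peaks(peaks, ann, atac, cells$barcode[cells$cell_type == t]))
tab <- cbind(all = strat_all, per_type)
write.table(round(t(tab), 2), "results/element_stratification.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
cat("element percentages (detected in > 10% of cells):\n")
print(round(t(tab), 1))

sets <- accessible_peak_sets(atac, cells$cell_type)
upset <- shared_unique_peaks(sets)
write.table(upset, "results/shared_unique_peaks.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nshared/unique accessible peaks:\n")
print(upset[order(-upset$count), ][1:10, ])

# standardized accessibility of the most variable gene-activity genes
act <- gene_activity(atac, peaks, ann, mode = "flank2kb")
types <- unique(cells$cell_type)
mean_act <- sapply(types, function(t)
  Matrix::rowMeans(act[, cells$cell_type == t, drop = FALSE]))
v <- apply(mean_act, 1, function(x) max(x) - min(x))
top <- names(sort(v, decreasing = TRUE))[1:13]
std <- t(apply(mean_act[top, ], 1, standardized_accessibility))
colnames(std) <- types
write.table(round(std, 3), "results/standardized_accessibility.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
cat("\nstandardized accessibility of the 13 most type-variable genes:\n")
print(round(std, 2))
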