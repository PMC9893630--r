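#!/usr/bin/env Rscript
# Step 5 — cis-regulatory peak-gene links and motif enrichment.
#
# Direct links: peaks whose interval contains a TSS. Co-enrichment links:
# same-type DE gene and specific peak within +/-100 kb of the TSS, with the
# TSS itself outside the peak. Motif enrichment: modified z-score of each
# motif in each type's specific peaks against the full peak universe.

suppressPackageStartupMessages(library(myomultiome))

peaks <- read_peaks_bed("results/data/peaks.bed")
ann <- read_annotation_gtf("results/data/annotation.gtf")
de <- read.delim("results/de_genes.tsv")
spec_df <- read.delim("results/specific_peaks.tsv")
occ <- read.delim("results/data/motif_occurrences.tsv")

types <- unique(spec_df$cell_type)
de_up <- setNames(lapply(types, function(t)
  de$feature_id[de$group_a == t & de$significant & de$logfc > 0]), types)
spec <- split(spec_df$peak_id, spec_df$cell_type)

direct <- link_direct(peaks, ann)
co <- link_coenrichment(de_up, spec, ann, peaks)
links <- rbind(direct, co)
write.table(links, "results/cis_links.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("direct TSS links:", nrow(direct),
    " co-enrichment links:", nrow(co), "\n")
cat("median |distance| of co-enrichment links (kb):",
    round(median(abs(co$distance_bp)) / 1000, 1), "\n")

zmat <- sapply(types, function(t)
  motif_zscore(spec[[t]], peaks$peak_id, occ))
write.table(round(zmat, 3), "results/motif_zscores.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
cat("\ntop motif per cell type by modified z-score:\n")
for (t in types)
  cat(sprintf("  %-6s %s (z = %.1f)\n", t, names(which.max(zmat[, t])),
              max(zmat[, t], na.rm = TRUE)))
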