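#!/usr/bin/env Rscript
# Step 1 — generate the paired multiome used by the rest of the workflow.
#
# Simulates four myogenic cell types (Pax3+ progenitor -> myogenic
# progenitor -> myoblast -> myocyte) along a linear pseudotime trajectory,
# with type-specific marker genes, type-specific accessible peaks, planted
# cis links, planted motifs, mitochondrial signal, doublets and 10x-style
# fragment records, and writes everything (plus the ground truth) under
# results/data/.

suppressPackageStartupMessages(library(myomultiome))

# a deeper genome than the package default so that absolute QC thresholds
# (200 genes detected, 2,000 fragments) are meaningful on simulated cells
cfg <- sim_config(seed = 20260927L, cells_per_type = 200, n_genes = 1000,
                  chrom_length = 3.5e7, fragments_per_cell = 3000)
ap <- simulate_annotation(cfg)
sim <- simulate_multiome(cfg, ap$annotation, ap$peaks)

outdir <- "results/data"
write_multiome(sim, ap$annotation, ap$peaks, outdir)

cat("genes:", nrow(ap$annotation$genes),
    " peaks:", nrow(ap$peaks),
    " cells:", nrow(sim$cells),
    " (doublets:", sum(sim$cells$doublet), ")\n")
cat("fragments:", nrow(sim$fragments), "\n")
cat("marker genes per type:",
    lengths(sim$truth$type_specific_genes), "\n")
cat("specific peaks per type:",
    lengths(sim$truth$type_specific_peaks), "\n")
cat("planted cis links:", nrow(sim$truth$planted_links), "\n")
cat("written to", outdir, "\n")
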