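test_that("annotation simulation is deterministic and well-formed", {
  cfg <- small_config()
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)

  g <- a1$annotation$genes
  ex <- a1$annotation$exons
  expect_true(all(g$start < g$end))
  # TSS = start on +, end-1 on -
  plus <- g$strand == "+"
  expect_equal(g$tss[plus], g$start[plus])
  expect_equal(g$tss[!plus], g$end[!plus] - 1)
  # exons inside gene bodies
  for (gid in g$gene_id) {
    e <- ex[ex$gene_id == gid, ]
    expect_true(all(e$start >= g$start[g$gene_id == gid]))
    expect_true(all(e$end <= g$end[g$gene_id == gid]))
  }
  # peaks have valid unique ids and sensible widths
  pk <- a1$peaks
  expect_true(all(pk$start < pk$end))
  expect_false(any(duplicated(pk$peak_id)))
})

test_that("every element class is represented among generated peaks", {
  d <- small_dataset()
  cls <- classify_peaks(d$peaks, d$annotation)
  expect_setequal(unique(cls),
                  c("exon", "promoter", "utr5", "utr3", "intron", "distal"))
  # agreement with the brute-force interval-scan oracle
  idx <- seq(1, nrow(d$peaks), by = 7)
  expect_identical(unname(cls[idx]),
                   brute_classify(d$peaks[idx, ], d$annotation))
})

test_that("a geneless genome classifies every peak as distal", {
  cfg <- sim_config(seed = 3, n_genes = 0, n_peaks = 100, chrom_length = 1e6)
  ap <- simulate_annotation(cfg)
  auto <- ap$peaks[ap$peaks$chrom == "chr1", ]
  expect_true(all(classify_peaks(auto, ap$annotation) == "distal"))
})

test_that("an overfull chromosome is rejected", {
  cfg <- sim_config(seed = 1, n_genes = 100, n_peaks = 10, chrom_length = 1e5)
  expect_error(simulate_annotation(cfg), "too short")
})

test_that("multiome counts honour the count-data contract", {
  d <- small_dataset()
  rna <- d$sim$rna
  expect_true(all(rna@x >= 0))
  expect_true(all(rna@x == round(rna@x)))
  expect_true(all(Matrix::colSums(rna) > 0))
  expect_identical(colnames(rna), d$sim$cells$barcode)
  expect_identical(colnames(d$sim$atac), d$sim$cells$barcode)
})

test_that("doublet_frac = 0 yields no doublet barcodes", {
  cfg <- small_config(doublet_frac = 0)
  ap <- simulate_annotation(cfg)
  sim <- simulate_multiome(cfg, ap$annotation, ap$peaks, with_fragments = FALSE)
  expect_length(sim$truth$doublet_barcodes, 0)
  expect_false(any(sim$cells$doublet))
})

test_that("planted peaks separate focal from background detection", {
  d <- small_dataset()
  sim <- d$sim
  singlets <- sim$cells$barcode[!sim$cells$doublet]
  labels <- sim$cells$cell_type[!sim$cells$doublet]
  atac <- sim$atac[, singlets]
  for (t in names(sim$truth$type_specific_peaks)) {
    ps <- sim$truth$type_specific_peaks[[t]]
    focal <- detection_fraction(atac[ps, , drop = FALSE], labels == t)
    bg <- detection_fraction(atac[ps, , drop = FALSE], labels != t)
    expect_gt(mean(focal) - mean(bg), 0.25)
    # marginals within 3 binomial SE of the configured probabilities
    n_f <- sum(labels == t)
    se_f <- sqrt(0.6 * 0.4 / n_f)
    expect_true(mean(abs(focal - 0.6) < 3 * se_f) > 0.9)
  }
})

test_that("planted links respect all three co-enrichment conditions", {
  d <- small_dataset()
  tr <- d$sim$truth
  pl <- tr$planted_links
  expect_gt(nrow(pl), 0)
  g <- d$annotation$genes
  pk <- d$peaks[match(pl$peak_id, d$peaks$peak_id), ]
  tss <- g$tss[match(pl$gene_id, g$gene_id)]
  # same-type specificity
  for (i in seq_len(nrow(pl))) {
    expect_true(pl$gene_id[i] %in% tr$type_specific_genes[[pl$cell_type[i]]])
    expect_true(pl$peak_id[i] %in% tr$type_specific_peaks[[pl$cell_type[i]]])
  }
  # in cis, not containing the TSS
  expect_true(all(pk$start <= tss + 1e5 & pk$end >= tss - 1e5))
  expect_false(any(pk$start <= tss & tss < pk$end))
  # type-specific feature sets disjoint across types
  expect_false(any(duplicated(unlist(tr$type_specific_genes))))
  expect_false(any(duplicated(unlist(tr$type_specific_peaks))))
})

test_that("fragment sizes are bimodal and multiome generation is deterministic", {
  cfg <- small_config(seed = 7, cells_per_type = 20)
  ap <- simulate_annotation(cfg)
  s1 <- simulate_multiome(cfg, ap$annotation, ap$peaks)
  s2 <- simulate_multiome(cfg, ap$annotation, ap$peaks)
  expect_identical(s1$rna, s2$rna)
  expect_identical(s1$fragments, s2$fragments)
  len <- s1$fragments$end - s1$fragments$start
  expect_gt(mean(len < 147), 0.4)            # sub-nucleosomal mode
  expect_gt(mean(len >= 147 & len <= 294), 0.2)  # mono-nucleosomal mode
  # insertions enriched near TSSs: mean TSS enrichment comfortably above 1
  qc <- compute_atac_qc(s1$fragments, ap$peaks, ap$annotation)
  expect_gt(mean(qc$tss_enrichment), 1.5)
})

test_that("trend profiles track their templates", {
  cfg <- sim_config(seed = 11, noise_sd = 0.2)
  tp <- simulate_trend_profiles(cfg, n_genes = 25, n_cells = 3000)
  s <- scale_pseudotime(tp$pseudotime)
  curves <- trend_curves(tp$expr, s, smooth = TRUE)
  grid <- (0:100) / 100
  tpl <- trend_templates(grid, cfg$n_trend_templates)
  for (g in rownames(curves)) {
    k <- tp$template_of_gene[[g]]
    expect_gt(stats::cor(curves[g, ], tpl[, k]), 0.9)
  }
})
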