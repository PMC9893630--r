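# Small deterministic fixtures shared across test files.

# a compact simulated dataset used by several modules
small_config <- function(seed = 42L, cells_per_type = 60, ...) {
  sim_config(seed = seed, cells_per_type = cells_per_type, n_genes = 60,
             n_peaks = 300, chrom_length = 3e6, fragments_per_cell = 1000, ...)
}

small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_config()
      ap <- simulate_annotation(cfg)
      sim <- simulate_multiome(cfg, ap$annotation, ap$peaks)
      cache <<- list(cfg = cfg, annotation = ap$annotation, peaks = ap$peaks,
                     sim = sim)
    }
    cache
  }
})

# hand-built two-gene annotation on one contig for interval tests:
# geneA (+): body [1000, 6000), exons [1000,1500) and [5500,6000),
#   utr5 [1000,1200), utr3 [5800,6000), TSS 1000
# geneB (-): body [20000, 26000), exons [20000,20600) and [25000,26000),
#   utr5 [25700,26000) (5' end is the right end), utr3 [20000,20200),
#   TSS 25999
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("geneA", "geneB"), chrom = "chr1", strand = c("+", "-"),
    start = c(1000, 20000), end = c(6000, 26000), tss = c(1000, 25999))
  exons <- data.frame(
    gene_id = c("geneA", "geneA", "geneB", "geneB"), chrom = "chr1",
    start = c(1000, 5500, 20000, 25000), end = c(1500, 6000, 20600, 26000))
  utr5 <- data.frame(gene_id = c("geneA", "geneB"), chrom = "chr1",
                     start = c(1000, 25700), end = c(1200, 26000))
  utr3 <- data.frame(gene_id = c("geneA", "geneB"), chrom = "chr1",
                     start = c(5800, 20000), end = c(6000, 20200))
  structure(list(genes = genes, exons = exons, utr5 = utr5, utr3 = utr3,
                 chroms = c(chr1 = 1e5)),
            class = "genome_annotation")
}

peak_row <- function(chrom, start, end, id = sprintf("%s:%d-%d", chrom, start, end)) {
  data.frame(peak_id = id, chrom = chrom, start = start, end = end)
}

# random toy genome for brute-force classification oracles
random_toy_genome <- function(seed, n_genes = 10, chrom_len = 2e6) {
  set.seed(seed)
  cfg <- sim_config(seed = seed, n_genes = n_genes, n_peaks = 200,
                    chrom_length = max(chrom_len, n_genes * 40000))
  simulate_annotation(cfg)
}

# quadratic brute-force element classification over explicit interval lists,
# independent of the package's findOverlaps-based path
brute_classify <- function(peaks, annotation, upstream = 2000) {
  ivs <- list()
  g <- annotation$genes
  # exon minus UTR, computed by per-base set arithmetic on small intervals
  for (i in seq_len(nrow(annotation$exons))) {
    e <- annotation$exons[i, ]
    bases <- seq(e$start, e$end - 1)
    u <- rbind(annotation$utr5[annotation$utr5$gene_id == e$gene_id, ],
               annotation$utr3[annotation$utr3$gene_id == e$gene_id, ])
    if (nrow(u) > 0) {
      ub <- unlist(lapply(seq_len(nrow(u)), function(j)
        seq(u$start[j], u$end[j] - 1)))
      bases <- setdiff(bases, ub)
    }
    if (length(bases))
      ivs$exon <- rbind(ivs$exon,
                        data.frame(chrom = e$chrom,
                                   start = min(bases), end = max(bases) + 1))
  }
  for (i in seq_len(nrow(g))) {
    pr <- promoter_of(g[i, ], upstream)
    if (pr[2] > pr[1])
      ivs$promoter <- rbind(ivs$promoter,
                            data.frame(chrom = g$chrom[i],
                                       start = pr[1], end = pr[2]))
  }
  ivs$utr5 <- annotation$utr5[, c("chrom", "start", "end")]
  ivs$utr3 <- annotation$utr3[, c("chrom", "start", "end")]
  ivs$intron <- g[, c("chrom", "start", "end")]
  overlaps_any <- function(p, df) {
    if (is.null(df) || nrow(df) == 0) return(FALSE)
    any(df$chrom == p$chrom & df$start < p$end & p$start < df$end)
  }
  vapply(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    for (cl in c("exon", "promoter", "utr5", "utr3", "intron"))
      if (overlaps_any(p, ivs[[cl]])) return(cl)
    "distal"
  }, character(1))
}
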