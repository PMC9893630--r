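#' Configuration for the synthetic paired-multiome generator
#'
#' Bundles every knob of the simulator into a validated list. The defaults
#' describe a desk-scale embryo-myogenesis-like dataset: four cell types
#' ordered along a linear differentiation trajectory (Pax3+ progenitor ->
#' myogenic progenitor -> myoblast -> myocyte), each with its own marker
#' genes and specifically accessible peaks, sparse negative-binomial RNA
#' counts, Bernoulli/Poisson peak fragment counts, a bimodal fragment-size
#' distribution and TSS-enriched insertion positions.
#'
#' @param seed integer; fully determines the generated dataset.
#' @param n_cell_types number of ordered cell types along the trajectory.
#' @param cells_per_type cells simulated per type (before doublets).
#' @param n_genes number of (non-mitochondrial) genes.
#' @param n_peaks number of open-chromatin peaks.
#' @param chrom_length main chromosome length in bp.
#' @param frac_marker_genes fraction of genes planted as markers of each type.
#' @param frac_specific_peaks fraction of peaks planted as specific to each type.
#' @param rna_mean_base expected baseline counts per gene per cell.
#' @param rna_dispersion negative-binomial size parameter.
#' @param marker_fold multiplicative lift of a marker gene in its focal type
#'   (at the peak of its trend template).
#' @param accessibility_p_base per-peak per-cell background detection probability.
#' @param accessibility_p_high detection probability of a planted peak in its
#'   focal type; must exceed `accessibility_p_base`.
#' @param mito_frac_mean mean mitochondrial fraction of RNA counts per cell.
#' @param atac_mito_mean mean fraction of ATAC fragments on the mitochondrial
#'   contig (typically much lower than the RNA mitochondrial fraction).
#' @param doublet_frac fraction of extra barcodes that are sums of two cells.
#' @param n_motifs number of motifs in the occurrence table; one motif is
#'   planted per cell type (present in 60% of that type's specific peaks vs a
#'   10% background rate).
#' @param n_trend_templates number of pseudotime trend templates (>= 2; the
#'   default 5 gives early-decreasing, mid-peak, broad-mid, late-rise-and-hold
#'   and terminal-only shapes).
#' @param noise_sd dimensionless Gaussian noise added around trend templates
#'   by [simulate_trend_profiles()].
#' @param fragments_per_cell mean number of ATAC fragments per cell.
#' @param frac_fragments_in_peaks fraction of a cell's fragments placed inside
#'   peaks (drives FRiP).
#' @param frac_fragments_tss fraction of a cell's fragments centred near a TSS
#'   (drives TSS enrichment).
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       n_cell_types = 4L,
                       cells_per_type = 500L,
                       n_genes = 200L,
                       n_peaks = 1000L,
                       chrom_length = 2e7,
                       frac_marker_genes = 0.10,
                       frac_specific_peaks = 0.05,
                       rna_mean_base = 0.5,
                       rna_dispersion = 2,
                       marker_fold = 8,
                       accessibility_p_base = 0.05,
                       accessibility_p_high = 0.60,
                       mito_frac_mean = 0.02,
                       atac_mito_mean = 0.005,
                       doublet_frac = 0.02,
                       n_motifs = 10L,
                       n_trend_templates = 5L,
                       noise_sd = 0.1,
                       fragments_per_cell = 3000,
                       frac_fragments_in_peaks = 0.65,
                       frac_fragments_tss = 0.25) {
  cfg <- list(
    seed = as.integer(seed), n_cell_types = as.integer(n_cell_types),
    cells_per_type = as.integer(cells_per_type), n_genes = as.integer(n_genes),
    n_peaks = as.integer(n_peaks), chrom_length = as.numeric(chrom_length),
    frac_marker_genes = frac_marker_genes,
    frac_specific_peaks = frac_specific_peaks,
    rna_mean_base = rna_mean_base, rna_dispersion = rna_dispersion,
    marker_fold = marker_fold,
    accessibility_p_base = accessibility_p_base,
    accessibility_p_high = accessibility_p_high,
    mito_frac_mean = mito_frac_mean, atac_mito_mean = atac_mito_mean,
    doublet_frac = doublet_frac, n_motifs = as.integer(n_motifs),
    n_trend_templates = as.integer(n_trend_templates), noise_sd = noise_sd,
    fragments_per_cell = fragments_per_cell,
    frac_fragments_in_peaks = frac_fragments_in_peaks,
    frac_fragments_tss = frac_fragments_tss)
  fracs <- c("frac_marker_genes", "frac_specific_peaks", "mito_frac_mean",
             "atac_mito_mean", "doublet_frac", "accessibility_p_base",
             "accessibility_p_high", "frac_fragments_in_peaks",
             "frac_fragments_tss")
  for (f in fracs)
    .assert(cfg[[f]] >= 0 && cfg[[f]] <= 1, paste0(f, " must be in [0,1]"))
  .assert(cfg$accessibility_p_high > cfg$accessibility_p_base,
          "accessibility_p_high must exceed accessibility_p_base")
  .assert(cfg$n_trend_templates >= 2L, "n_trend_templates must be >= 2")
  .assert(cfg$n_cell_types >= 2L, "n_cell_types must be >= 2")
  .assert(cfg$noise_sd >= 0, "noise_sd must be non-negative")
  structure(cfg, class = "sim_config")
}

#' Pseudotime trend templates
#'
#' Evaluates the planted trend templates at scaled pseudotime values.
#' With the default of five templates the shapes are: (1) early-high
#' decreasing, (2) mid-early peak, (3) broad mid, (4) late rise-and-hold,
#' (5) terminal-only. For other template counts, Gaussian bumps with centres
#' spread evenly over [0,1] are used. All templates take values in [0,1].
#'
#' @param s numeric vector of scaled pseudotime in [0,1].
#' @param k number of templates.
#' @return a length(s) x k matrix of template values.
#' @export
trend_templates <- function(s, k = 5L) {
  .assert(all(s >= 0 & s <= 1), "scaled pseudotime must lie in [0,1]")
  if (k == 5L) {
    m <- cbind(
      exp(-(s / 0.25)^2),                 # early-high decreasing
      exp(-((s - 0.35) / 0.12)^2),        # mid-early peak
      exp(-((s - 0.55) / 0.28)^2),        # broad mid
      stats::plogis((s - 0.65) / 0.06),   # late rise and hold
      exp(-((s - 1) / 0.10)^2))           # terminal-only
  } else {
    centers <- seq(0, 1, length.out = k)
    m <- sapply(centers, function(ce) exp(-((s - ce) / 0.15)^2))
    m <- matrix(m, nrow = length(s))
  }
  colnames(m) <- paste0("template", seq_len(ncol(m)))
  m
}

# pseudotime position (in [0,1]) where each template peaks; used to match
# templates to cell types along the trajectory
.template_argmax <- function(k) {
  grid <- seq(0, 1, length.out = 1001)
  vals <- trend_templates(grid, k)
  grid[apply(vals, 2, which.max)]
}
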