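#' Per-cell RNA quality-control metrics
#'
#' Computes, per barcode: the number of genes detected (count > 0), the UMI
#' total, the fraction of counts on mitochondrial features, and a doublet
#' flag raised for barcodes with more than 40,000 transcripts. All-zero
#' cells get `mito_fraction = 0` (they fall to the gene-count filter anyway).
#'
#' @param rna gene x cell count matrix (dgCMatrix or matrix) with rownames.
#' @param mito_feature_ids character vector of mitochondrial feature ids;
#'   must all be present among the rownames.
#' @param doublet_umi doublet-flag threshold on the UMI total (strictly
#'   greater-than; default 40000).
#' @return data.frame: barcode, n_genes_detected, n_umis, mito_fraction,
#'   doublet_flag.
#' @export
compute_rna_qc <- function(rna, mito_feature_ids = character(0),
                           doublet_umi = 40000) {
  .assert(!is.null(rownames(rna)), "rna matrix must have feature rownames")
  unknown <- setdiff(mito_feature_ids, rownames(rna))
  if (length(unknown))
    stop("unknown mitochondrial feature id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n_umis <- Matrix::colSums(rna)
  n_genes <- Matrix::colSums(rna > 0)
  mito <- if (length(mito_feature_ids))
    Matrix::colSums(rna[mito_feature_ids, , drop = FALSE]) else rep(0, ncol(rna))
  mito_fraction <- ifelse(n_umis > 0, mito / n_umis, 0)
  data.frame(barcode = colnames(rna),
             n_genes_detected = as.integer(n_genes),
             n_umis = as.numeric(n_umis),
             mito_fraction = as.numeric(mito_fraction),
             doublet_flag = n_umis > doublet_umi,
             row.names = NULL)
}

#' Filter an RNA count matrix on per-cell QC
#'
#' A cell is removed when it has fewer than `min_genes` genes detected, more
#' than `max_umis` UMIs, a mitochondrial fraction above `max_mito`, or a
#' raised doublet flag. Features detected (count > 0) in fewer than
#' `min_cells` surviving cells are then removed (exactly `min_cells`
#' survivors retains the feature).
#'
#' @param rna gene x cell count matrix.
#' @param qc output of [compute_rna_qc()] aligned to `colnames(rna)`.
#' @param min_genes,max_umis,max_mito,min_cells filter thresholds
#'   (defaults 200, 30000, 0.10, 3).
#' @return list: `matrix` (filtered), `report` (named counts removed per
#'   criterion; a cell can be counted under several criteria).
#' @export
filter_rna <- function(rna, qc, min_genes = 200, max_umis = 30000,
                       max_mito = 0.10, min_cells = 3) {
  .assert(identical(qc$barcode, colnames(rna)),
          "qc table must be aligned to matrix barcodes")
  low_genes <- qc$n_genes_detected < min_genes
  high_umis <- qc$n_umis > max_umis
  high_mito <- qc$mito_fraction > max_mito
  doublet <- qc$doublet_flag
  remove <- low_genes | high_umis | high_mito | doublet
  kept <- rna[, !remove, drop = FALSE]
  detected_in <- Matrix::rowSums(kept > 0)
  feat_drop <- detected_in < min_cells
  kept <- kept[!feat_drop, , drop = FALSE]
  list(matrix = kept,
       report = c(cells_low_genes = sum(low_genes),
                  cells_high_umis = sum(high_umis),
                  cells_high_mito = sum(high_mito),
                  cells_doublet = sum(doublet),
                  cells_removed = sum(remove),
                  cells_kept = sum(!remove),
                  features_removed = sum(feat_drop),
                  features_kept = sum(!feat_drop)))
}

#' Per-cell ATAC quality-control metrics from fragment records
#'
#' Computes per barcode: the number of fragments, the fraction on the
#' mitochondrial contig, the TSS enrichment score, the nucleosome signal and
#' FRiP (fraction of fragments overlapping peaks by at least one base).
#'
#' The nucleosome signal is the count of mono-nucleosomal fragments
#' (147-294 bp) over the count of sub-nucleosomal fragments (< 147 bp), with
#' the denominator floored at 1. The TSS enrichment score treats both
#' fragment ends as insertion events, collects insertions within 1 kb of any
#' TSS (signed, strand-aware distance), and compares the mean per-base
#' insertion count in the central +/-500 bp to the mean over the outermost
#' 100-bp flanks; a pseudocount of half the cell's mean per-base count over
#' the window is added to both, so a cell with uniform insertions scores ~1.
#' Barcodes with zero fragments score 0 on all metrics.
#'
#' @param fragments data.frame/data.table with chrom, start, end, barcode
#'   (0-based half-open).
#' @param peaks peak data frame (peak_id, chrom, start, end).
#' @param annotation a `genome_annotation` (TSS source).
#' @param mito_contig name of the mitochondrial contig (default "chrM").
#' @param barcodes optional barcode universe; barcodes absent from the
#'   fragment file get zero-rows.
#' @return data.frame: barcode, n_fragments, mito_ratio, tss_enrichment,
#'   nucleosome_signal, frip.
#' @export
compute_atac_qc <- function(fragments, peaks, annotation,
                            mito_contig = "chrM", barcodes = NULL) {
  frag <- data.table::as.data.table(fragments)
  if (is.null(barcodes)) barcodes <- sort(unique(frag$barcode))
  bc <- factor(frag$barcode, levels = barcodes)
  keep <- which(!is.na(bc))
  frag <- frag[keep, ]; bc <- bc[keep]

  n_fragments <- tabulate(bc, nbins = length(barcodes))
  mito <- tabulate(bc[frag$chrom == mito_contig], nbins = length(barcodes))
  mito_ratio <- ifelse(n_fragments > 0, mito / n_fragments, 0)

  len <- frag$end - frag$start
  mono <- tabulate(bc[len >= 147 & len <= 294], nbins = length(barcodes))
  sub <- tabulate(bc[len < 147], nbins = length(barcodes))
  nucleosome_signal <- ifelse(n_fragments > 0, mono / pmax(1, sub), 0)

  in_peak <- .count_overlaps(
    .gr(frag$chrom, frag$start, frag$end),
    .gr(peaks$chrom, peaks$start, peaks$end), minoverlap = 1L) > 0
  frip <- ifelse(n_fragments > 0,
                 tabulate(bc[in_peak], nbins = length(barcodes)) / n_fragments, 0)

  tss_enrichment <- .tss_enrichment(frag, bc, length(barcodes), annotation)
  tss_enrichment[n_fragments == 0] <- 0

  data.frame(barcode = barcodes, n_fragments = n_fragments,
             mito_ratio = as.numeric(mito_ratio),
             tss_enrichment = as.numeric(tss_enrichment),
             nucleosome_signal = as.numeric(nucleosome_signal),
             frip = as.numeric(frip), row.names = NULL)
}

# per-cell TSS enrichment from insertion events (both fragment ends)
.tss_enrichment <- function(frag, bc, n_bc, annotation, flank = 1000L,
                            central = 500L, edge = 100L) {
  g <- annotation$genes
  g <- g[g$chrom %in% unique(frag$chrom), , drop = FALSE]
  if (nrow(g) == 0) return(rep(0, n_bc))
  # insertion positions: start and end-1 (last covered base)
  ins_pos <- c(frag$start, frag$end - 1L)
  ins_chr <- c(frag$chrom, frag$chrom)
  ins_bc <- c(as.integer(bc), as.integer(bc))
  win <- .gr(g$chrom, pmax(0, g$tss - flank), g$tss + flank + 1)
  hits <- .find_overlaps(.gr(ins_chr, ins_pos, ins_pos + 1L), win)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  d <- (ins_pos[qi] - g$tss[si]) * ifelse(g$strand[si] == "+", 1L, -1L)
  cell <- ins_bc[qi]
  absd <- abs(d)
  n_sig <- tabulate(cell[absd <= central], nbins = n_bc)
  n_bgd <- tabulate(cell[absd > flank - edge & absd <= flank], nbins = n_bc)
  n_tot <- tabulate(cell, nbins = n_bc)
  sig <- n_sig / (2 * central + 1)
  bgd <- n_bgd / (2 * edge)
  pc <- 0.5 * n_tot / (2 * flank + 1)
  out <- ifelse(n_tot > 0, (sig + pc) / (bgd + pc), 0)
  out
}

#' Filter an ATAC count matrix on per-cell QC
#'
#' A barcode is kept iff its fragment count lies in `[min_fragments,
#' max_fragments]`, its mitochondrial ratio is below `max_mito`, its TSS
#' enrichment lies strictly between `tss_min` and `tss_max`, its nucleosome
#' signal is below `max_nucleosome` and its FRiP is strictly above
#' `min_frip`.
#'
#' @param atac peak x cell count matrix.
#' @param qc output of [compute_atac_qc()] aligned to `colnames(atac)`.
#' @param min_fragments,max_fragments,max_mito,tss_min,tss_max,max_nucleosome,min_frip
#'   thresholds (defaults 2000, 30000, 0.02, 2, 40, 5, 0.50).
#' @return list: `matrix` (filtered), `report` (counts failing each rule).
#' @export
filter_atac <- function(atac, qc, min_fragments = 2000, max_fragments = 30000,
                        max_mito = 0.02, tss_min = 2, tss_max = 40,
                        max_nucleosome = 5, min_frip = 0.50) {
  .assert(identical(qc$barcode, colnames(atac)),
          "qc table must be aligned to matrix barcodes")
  bad_frag <- qc$n_fragments < min_fragments | qc$n_fragments > max_fragments
  bad_mito <- !(qc$mito_ratio < max_mito)
  bad_tss <- !(qc$tss_enrichment > tss_min & qc$tss_enrichment < tss_max)
  bad_ns <- !(qc$nucleosome_signal < max_nucleosome)
  bad_frip <- !(qc$frip > min_frip)
  remove <- bad_frag | bad_mito | bad_tss | bad_ns | bad_frip
  list(matrix = atac[, !remove, drop = FALSE],
       report = c(cells_bad_fragments = sum(bad_frag),
                  cells_bad_mito = sum(bad_mito),
                  cells_bad_tss = sum(bad_tss),
                  cells_bad_nucleosome = sum(bad_ns),
                  cells_bad_frip = sum(bad_frip),
                  cells_removed = sum(remove),
                  cells_kept = sum(!remove)))
}
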