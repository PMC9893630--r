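#' Genomic element classification and peak stratification
#'
#' Internally every interval is 0-based half-open. Peak element classes are
#' assigned by a fixed priority order, exon > promoter > 5'-UTR > 3'-UTR >
#' intron > distal, where "overlap" means at least one shared base. Exon here
#' means the CDS-bearing exon body: where UTR annotation exists, the UTR
#' portions of terminal exons are carved out and compete as their own
#' classes; where a gene has no UTR annotation its whole exons count as exon.
#'
#' @name element-classification
NULL

#' Promoter interval of a gene
#'
#' The promoter is the 2-kb region immediately upstream of the TSS,
#' strand-aware and clipped at position 0: on `+`, `[TSS-2000, TSS)`; on `-`,
#' `[TSS+1, TSS+2001)` (the TSS of a minus-strand gene is its last base,
#' `end - 1`).
#'
#' @param gene one-row data frame with `strand`, `tss` (and optionally
#'   `chrom`), or a `genome_annotation` plus `gene_id`.
#' @param upstream promoter length in bp (default 2000).
#' @return numeric `c(start, end)` in 0-based half-open coordinates.
#' @export
promoter_of <- function(gene, upstream = 2000) {
  .assert(nrow(gene) == 1 && gene$strand %in% c("+", "-"),
          "gene must be a one-row record with a valid strand")
  if (gene$strand == "+") {
    c(max(0, gene$tss - upstream), gene$tss)
  } else {
    c(gene$tss + 1, gene$tss + 1 + upstream)
  }
}

# promoter intervals for all genes -> data.frame(gene_id, chrom, start, end)
.promoters_df <- function(annotation, upstream = 2000) {
  g <- annotation$genes
  if (nrow(g) == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0)))
  plus <- g$strand == "+"
  start <- ifelse(plus, pmax(0, g$tss - upstream), g$tss + 1)
  end <- ifelse(plus, g$tss, g$tss + 1 + upstream)
  keep <- end > start
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = start, end = end)[keep, , drop = FALSE]
}

# exon intervals with UTR sub-intervals carved out (per gene); genes without
# UTR annotation keep whole exons
.exon_cds_df <- function(annotation) {
  ex <- annotation$exons
  if (nrow(ex) == 0) return(ex)
  utr <- rbind(annotation$utr5, annotation$utr3)
  utr <- utr[!is.na(utr$start), , drop = FALSE]
  if (nrow(utr) == 0) return(ex)
  out <- vector("list", 0)
  for (gid in unique(ex$gene_id)) {
    e <- ex[ex$gene_id == gid, , drop = FALSE]
    u <- utr[utr$gene_id == gid, , drop = FALSE]
    if (nrow(u) == 0) { out[[length(out) + 1]] <- e; next }
    kept <- IRanges::setdiff(.ir(e$start, e$end), .ir(u$start, u$end))
    if (length(kept) == 0) next
    out[[length(out) + 1]] <- data.frame(
      gene_id = gid, chrom = e$chrom[1],
      start = IRanges::start(kept) - 1L, end = IRanges::end(kept))
  }
  if (length(out) == 0)
    return(ex[0, , drop = FALSE])
  do.call(rbind, out)
}

# element intervals by priority class, built once per annotation
.element_index <- function(annotation, upstream = 2000) {
  list(exon = .exon_cds_df(annotation),
       promoter = .promoters_df(annotation, upstream),
       utr5 = annotation$utr5,
       utr3 = annotation$utr3,
       body = annotation$genes[, c("gene_id", "chrom", "start", "end")])
}

#' Classify peaks into genomic element classes
#'
#' Assigns each peak the highest-priority element class it overlaps by at
#' least one base: exon > promoter > 5'-UTR > 3'-UTR > intron > distal.
#' A peak overlapping a gene body but none of the higher classes is an
#' intron peak; a peak overlapping nothing is distal.
#'
#' @param peaks data frame with `peak_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param annotation a `genome_annotation`.
#' @param upstream promoter length in bp.
#' @return character vector of classes, named by `peak_id`.
#' @export
classify_peaks <- function(peaks, annotation, upstream = 2000) {
  .assert(all(peaks$chrom %in% names(annotation$chroms)),
          "peak on unknown contig")
  idx <- .element_index(annotation, upstream)
  cls <- rep("distal", nrow(peaks))
  pk_gr <- .gr(peaks$chrom, peaks$start, peaks$end)
  order <- c("exon", "promoter", "utr5", "utr3", "body")
  labels <- c(exon = "exon", promoter = "promoter", utr5 = "utr5",
              utr3 = "utr3", body = "intron")
  for (cl in rev(order)) {  # low priority first; high priority overwrites
    iv <- idx[[cl]]
    if (is.null(iv) || nrow(iv) == 0) next
    hit <- .count_overlaps(pk_gr, .gr(iv$chrom, iv$start, iv$end),
                                        minoverlap = 1L) > 0
    cls[hit] <- labels[[cl]]
  }
  stats::setNames(cls, peaks$peak_id)
}

#' Classify a single peak
#'
#' @param peak one-row peak data frame.
#' @inheritParams classify_peaks
#' @return a single element class label.
#' @export
classify_peak <- function(peak, annotation, upstream = 2000) {
  unname(classify_peaks(peak[1, , drop = FALSE], annotation, upstream))
}

#' Stratify detected peaks into element-class percentages
#'
#' Restricts to peaks detected (fragment count > 0) in more than `min_pct` of
#' the selected cells, classifies each and returns the percentage of peaks
#' per element class (summing to 100).
#'
#' @param peaks peak data frame.
#' @param annotation a `genome_annotation`.
#' @param atac peak x cell count matrix (rows named by `peak_id`).
#' @param cells character or integer index of the cell subset.
#' @param min_pct detection-fraction cutoff; strictly greater-than (default 0.10).
#' @return named numeric vector over all six classes, in percent.
#' @export
stratify_peaks <- function(peaks, annotation, atac, cells,
                           min_pct = 0.10) {
  .assert(length(cells) > 0, "empty cell subset")
  sub <- atac[peaks$peak_id, cells, drop = FALSE]
  frac <- Matrix::rowSums(sub > 0) / length(cells)
  kept <- peaks[frac > min_pct, , drop = FALSE]
  classes <- c("exon", "promoter", "utr5", "utr3", "intron", "distal")
  out <- stats::setNames(numeric(length(classes)), classes)
  if (nrow(kept) == 0) return(out)
  tab <- table(factor(classify_peaks(kept, annotation), levels = classes))
  out[] <- 100 * as.numeric(tab) / nrow(kept)
  out
}
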