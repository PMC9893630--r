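#' Direct cis-regulatory links: peaks containing a TSS
#'
#' A peak is linked to a gene when the peak interval contains the gene's TSS
#' coordinate under half-open containment (`start <= TSS < end`).
#'
#' @param peaks peak data frame (peak_id, chrom, start, end).
#' @param annotation a `genome_annotation`.
#' @return data.frame: gene_id, peak_id, method = "direct", cell_type = NA,
#'   distance_bp (signed TSS-to-peak-midpoint offset; positive downstream of
#'   the TSS in the gene's orientation).
#' @export
link_direct <- function(peaks, annotation) {
  g <- annotation$genes
  hits <- .find_overlaps(
    .gr(g$chrom, g$tss, g$tss + 1),
    .gr(peaks$chrom, peaks$start, peaks$end))
  gi <- S4Vectors::queryHits(hits); pi <- S4Vectors::subjectHits(hits)
  mid <- (peaks$start[pi] + peaks$end[pi]) / 2
  sgn <- ifelse(g$strand[gi] == "+", 1, -1)
  data.frame(gene_id = g$gene_id[gi], peak_id = peaks$peak_id[pi],
             method = rep_len("direct", length(gi)),
             cell_type = rep_len(NA_character_, length(gi)),
             distance_bp = (mid - g$tss[gi]) * sgn, row.names = NULL)
}

#' Co-enrichment cis-regulatory links
#'
#' Links a gene and a peak when (1) both are specific to the same cell type,
#' (2) they are in cis — the peak overlaps the closed window of +/- `window`
#' bp around the gene's TSS — and (3) the peak does not directly contain the
#' TSS. Many-to-many links are allowed.
#'
#' @param type_specific_genes named list: type -> gene-id vector (from
#'   differential expression).
#' @param type_specific_peaks named list: type -> peak-id vector (from
#'   differential accessibility).
#' @param annotation a `genome_annotation`; every listed gene needs a TSS.
#' @param peaks peak data frame.
#' @param window cis window half-width in bp (default 1e5).
#' @return data.frame: gene_id, peak_id, method = "coenrich", cell_type,
#'   distance_bp (signed, strand-aware TSS-to-midpoint offset).
#' @export
link_coenrichment <- function(type_specific_genes, type_specific_peaks,
                              annotation, peaks, window = 1e5) {
  g <- annotation$genes
  shared <- intersect(names(type_specific_genes), names(type_specific_peaks))
  out <- list()
  for (t in shared) {
    gs <- type_specific_genes[[t]]
    ps <- type_specific_peaks[[t]]
    if (length(gs) == 0 || length(ps) == 0) next
    gi0 <- match(gs, g$gene_id)
    if (anyNA(gi0))
      stop("gene without annotation/TSS: ",
           paste(gs[is.na(gi0)], collapse = ", "), call. = FALSE)
    pk <- peaks[match(ps, peaks$peak_id), , drop = FALSE]
    tssv <- g$tss[gi0]
    # closed window [TSS-window, TSS+window]: half-open rep. ends at +window+1
    hits <- .find_overlaps(
      .gr(g$chrom[gi0], pmax(0, tssv - window), tssv + window + 1),
      .gr(pk$chrom, pk$start, pk$end))
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    contains <- pk$start[si] <= tssv[qi] & tssv[qi] < pk$end[si]
    qi <- qi[!contains]; si <- si[!contains]
    if (length(qi) == 0) next
    mid <- (pk$start[si] + pk$end[si]) / 2
    sgn <- ifelse(g$strand[gi0][qi] == "+", 1, -1)
    out[[t]] <- data.frame(gene_id = gs[qi], peak_id = pk$peak_id[si],
                           method = "coenrich", cell_type = t,
                           distance_bp = (mid - tssv[qi]) * sgn,
                           row.names = NULL)
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(0), peak_id = character(0),
                      method = character(0), cell_type = character(0),
                      distance_bp = numeric(0)))
  do.call(rbind, out)
}
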