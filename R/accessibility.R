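#' Gene activity scores from peak fragment counts
#'
#' For each gene a window is formed from the gene body plus a 2-kb
#' extension — strand-aware upstream only (`upstream2kb`, the default) or
#' both flanks (`flank2kb`) — and the fragment counts of every peak
#' overlapping the window (by >= 1 bp) are summed per cell. A peak
#' overlapping several gene windows contributes to each of them.
#'
#' @param atac peak x cell count matrix with `peak_id` rownames.
#' @param peaks peak data frame (peak_id, chrom, start, end).
#' @param annotation a `genome_annotation`.
#' @param mode window mode, `"upstream2kb"` or `"flank2kb"`.
#' @param genes optional gene-id subset; an unknown id is an error.
#' @param drop_xym drop genes on sex and mitochondrial contigs
#'   (chrX/chrY/chrM and X/Y/MT spellings).
#' @param extend window extension in bp (default 2000).
#' @return gene x cell sparse matrix of activity scores.
#' @export
gene_activity <- function(atac, peaks, annotation,
                          mode = c("upstream2kb", "flank2kb"),
                          genes = NULL, drop_xym = FALSE, extend = 2000) {
  mode <- match.arg(mode)
  g <- annotation$genes
  if (!is.null(genes)) {
    missing <- setdiff(genes, g$gene_id)
    if (length(missing))
      stop("gene(s) absent from annotation: ",
           paste(missing, collapse = ", "), call. = FALSE)
    g <- g[g$gene_id %in% genes, , drop = FALSE]
  }
  if (drop_xym)
    g <- g[!g$chrom %in% c("chrX", "chrY", "chrM", "X", "Y", "MT"), ,
           drop = FALSE]
  plus <- g$strand == "+"
  if (mode == "upstream2kb") {
    ws <- ifelse(plus, pmax(0, g$start - extend), g$start)
    we <- ifelse(plus, g$end, g$end + extend)
  } else {
    ws <- pmax(0, g$start - extend)
    we <- g$end + extend
  }
  hits <- .find_overlaps(.gr(g$chrom, ws, we),
                                      .gr(peaks$chrom, peaks$start, peaks$end),
                                      minoverlap = 1L)
  gi <- S4Vectors::queryHits(hits)
  pi <- match(peaks$peak_id[S4Vectors::subjectHits(hits)], rownames(atac))
  ok <- !is.na(pi)
  ind <- Matrix::sparseMatrix(i = gi[ok], j = pi[ok], x = 1,
                              dims = c(nrow(g), nrow(atac)),
                              dimnames = list(g$gene_id, rownames(atac)))
  act <- ind %*% atac
  methods::as(act, "CsparseMatrix")
}

#' Standardize a per-cluster accessibility vector to [0,1]
#'
#' Subtracts the minimum and divides by the maximum of the min-subtracted
#' values, so the minimum maps to 0 and the maximum to 1. A constant input
#' returns all zeros with a warning.
#'
#' @param x numeric vector of per-cluster mean accessibility (length >= 2).
#' @return numeric vector in [0,1].
#' @export
standardized_accessibility <- function(x) {
  .assert(length(x) >= 2, "need at least two clusters")
  rng <- max(x) - min(x)
  if (rng == 0) {
    warning("constant accessibility vector; returning zeros")
    return(x * 0)
  }
  (x - min(x)) / rng
}
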