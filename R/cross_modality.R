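#' Select highly variable genes by binned standardized dispersion
#'
#' Genes are binned (20 equal-frequency bins) by mean normalized expression;
#' within each bin the dispersion (variance over mean) is z-scored, and the
#' top `n` genes by standardized dispersion are returned. Genes with zero
#' mean or zero variance are never selected ahead of variable ones.
#'
#' @param norm normalized gene x cell matrix.
#' @param n number of genes to select (must be in [1, nrow]).
#' @param bins number of mean-expression bins (default 20).
#' @return character vector of gene ids, ordered by decreasing dispersion.
#' @export
variable_genes <- function(norm, n = 2000, bins = 20) {
  .assert(n >= 1, "n must be positive")
  n <- min(n, nrow(norm))
  mu <- Matrix::rowMeans(norm)
  ex2 <- Matrix::rowMeans(norm^2)
  v <- pmax(0, (ex2 - mu^2) * ncol(norm) / max(1, ncol(norm) - 1))
  disp <- ifelse(mu > 0, v / mu, 0)
  # with few genes, shrink the bin count so each bin can hold several genes
  bins <- max(1, min(bins, floor(nrow(norm) / 5)))
  qs <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = bins + 1)))
  bin <- cut(mu, breaks = qs, include.lowest = TRUE)
  z <- stats::ave(disp, bin, FUN = function(d) {
    s <- stats::sd(d)
    if (is.na(s) || s == 0) d * 0 else (d - mean(d)) / s
  })
  z[v == 0] <- -Inf
  ord <- order(z, decreasing = TRUE)
  rownames(norm)[ord[seq_len(n)]]
}

#' Cross-modality correlation confusion matrix
#'
#' For every ATAC cell type r and RNA cell type c, computes the Pearson
#' correlation over the selected genes between the mean gene activity of
#' type r and the mean expression of type c. The predicted RNA type of each
#' ATAC type is the column argmax of its row.
#'
#' @param activity gene x cell activity matrix (ATAC side).
#' @param rna gene x cell normalized expression matrix.
#' @param atac_labels,rna_labels per-cell type labels aligned to the columns
#'   of `activity` / `rna`.
#' @param genes gene set used for the correlation; at least 3 genes must be
#'   present in both matrices.
#' @return list: `matrix` (ATAC types x RNA types Pearson correlations) and
#'   `predicted` (named character vector, ATAC type -> argmax RNA type).
#' @export
correlation_confusion <- function(activity, rna, atac_labels, rna_labels,
                                  genes) {
  shared <- intersect(intersect(genes, rownames(activity)), rownames(rna))
  if (length(shared) < 3)
    stop("fewer than 3 shared genes between modalities", call. = FALSE)
  at <- unique(atac_labels); rt <- unique(rna_labels)
  ma <- sapply(at, function(t)
    Matrix::rowMeans(activity[shared, atac_labels == t, drop = FALSE]))
  mr <- sapply(rt, function(t)
    Matrix::rowMeans(rna[shared, rna_labels == t, drop = FALSE]))
  cc <- stats::cor(as.matrix(ma), as.matrix(mr))
  rownames(cc) <- at; colnames(cc) <- rt
  pred <- stats::setNames(rt[apply(cc, 1, which.max)], at)
  list(matrix = cc, predicted = pred)
}
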