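#' Scale pseudotime to the [0,100] interval
#'
#' Linear map `s = 100 * (t - min t) / (max t - min t)`. Invariant under
#' affine transformation of the input; constant input is an error.
#'
#' @param t per-cell pseudotime (at least two distinct values).
#' @return numeric vector in [0,100].
#' @export
scale_pseudotime <- function(t) {
  rng <- range(t)
  if (rng[1] == rng[2])
    stop("pseudotime is constant; cannot scale", call. = FALSE)
  100 * (t - rng[1]) / (rng[2] - rng[1])
}

#' Per-unit mean expression curves along pseudotime
#'
#' Scaled pseudotime is partitioned into 101 integer units (`floor(s)`, with
#' s = 100 assigned to unit 100). The curve value of a gene at a unit is the
#' mean normalized expression over the cells in that unit; empty units are
#' filled by linear interpolation between the nearest non-empty units (the
#' nearest value at the ends). An optional centred moving average (window 5,
#' on by default) smooths each curve; partial windows at the edges use the
#' available values.
#'
#' @param norm normalized gene x cell matrix.
#' @param s scaled pseudotime in [0,100], aligned to columns.
#' @param genes optional gene subset.
#' @param smooth apply moving-average smoothing (default TRUE).
#' @param window smoothing window in units (default 5).
#' @return gene x 101 matrix (columns named "0".."100").
#' @export
trend_curves <- function(norm, s, genes = NULL, smooth = TRUE, window = 5) {
  .assert(all(s >= 0 & s <= 100), "scaled pseudotime must lie in [0,100]")
  if (is.null(genes)) genes <- rownames(norm)
  m <- norm[genes, , drop = FALSE]
  unit <- pmin(100L, as.integer(floor(s)))
  fu <- factor(unit, levels = 0:100)
  counts <- as.integer(table(fu))
  if (all(counts == 0)) stop("all pseudotime units empty", call. = FALSE)
  # per-unit sums via indicator matrix, then means over non-empty units
  ind <- Matrix::sparseMatrix(i = seq_along(unit), j = unit + 1L, x = 1,
                              dims = c(length(unit), 101L))
  sums <- as.matrix(m %*% ind)
  curve <- sweep(sums, 2, pmax(1L, counts), "/")
  curve[, counts == 0] <- NA_real_
  filled <- t(apply(curve, 1, .fill_linear))
  if (smooth) filled <- t(apply(filled, 1, .moving_average, window = window))
  dimnames(filled) <- list(genes, as.character(0:100))
  filled
}

# linear interpolation of interior NAs; nearest value at the ends
.fill_linear <- function(v) {
  if (!anyNA(v)) return(v)
  idx <- which(!is.na(v))
  stats::approx(idx, v[idx], xout = seq_along(v), rule = 2)$y
}

# centred moving average with shrinking windows at the edges
.moving_average <- function(v, window = 5) {
  h <- floor(window / 2)
  n <- length(v)
  vapply(seq_len(n), function(i)
    mean(v[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Cluster pseudotime trend curves
#'
#' Each curve is z-scored across units, curves are clustered by agglomerative
#' hierarchical clustering (Ward linkage on Euclidean distance) and the tree
#' is cut at k clusters. Clusters are renumbered by the ascending pseudotime
#' position of their mean curve's maximum, so cluster 1 peaks earliest.
#'
#' @param curves gene x unit matrix from [trend_curves()].
#' @param k number of clusters (default 5; must not exceed the gene count).
#' @return list: `labels` (named integer vector), `means` (k x units matrix
#'   of cluster mean z-scored curves).
#' @export
cluster_trends <- function(curves, k = 5) {
  .assert(nrow(curves) >= k, "k exceeds the number of genes")
  z <- t(apply(curves, 1, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) v * 0 else (v - mean(v)) / s
  }))
  if (k == 1) {
    labels <- stats::setNames(rep(1L, nrow(curves)), rownames(curves))
    return(list(labels = labels,
                means = matrix(colMeans(z), 1,
                               dimnames = list("1", colnames(curves)))))
  }
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  means <- do.call(rbind, lapply(seq_len(k), function(cl)
    colMeans(z[raw == cl, , drop = FALSE])))
  ord <- order(apply(means, 1, which.max))
  relabel <- match(raw, ord)
  means <- means[ord, , drop = FALSE]
  dimnames(means) <- list(seq_len(k), colnames(curves))
  list(labels = stats::setNames(as.integer(relabel), rownames(curves)),
       means = means)
}

#' Cell-cycle phase scores and phase calls
#'
#' Expression of every gene is z-scored across cells; a cell's S and G2M
#' scores are the means of the z-scores over the respective gene sets. A
#' cell is G1 when both scores are <= 0, otherwise the phase with the larger
#' score (ties go to S).
#'
#' @param norm normalized gene x cell matrix.
#' @param s_genes,g2m_genes non-empty gene-id sets; genes absent from the
#'   matrix are dropped, and a fully absent set is an error.
#' @return data.frame: barcode, s_score, g2m_score, phase.
#' @export
phase_scores <- function(norm, s_genes, g2m_genes) {
  zmean <- function(set, label) {
    present <- intersect(set, rownames(norm))
    if (length(present) == 0)
      stop(label, " gene set entirely absent from the matrix", call. = FALSE)
    m <- as.matrix(norm[present, , drop = FALSE])
    z <- t(apply(m, 1, function(v) {
      s <- stats::sd(v)
      if (is.na(s) || s == 0) v * 0 else (v - mean(v)) / s
    }))
    colMeans(z)
  }
  s_score <- zmean(s_genes, "S")
  g2m_score <- zmean(g2m_genes, "G2M")
  phase <- ifelse(s_score <= 0 & g2m_score <= 0, "G1",
           ifelse(s_score >= g2m_score, "S", "G2M"))
  data.frame(barcode = colnames(norm), s_score = as.numeric(s_score),
             g2m_score = as.numeric(g2m_score), phase = phase,
             row.names = NULL)
}

#' Phase proportions by cell state
#'
#' @param phases per-cell phase labels.
#' @param states aligned per-cell state labels; empty states are dropped
#'   with a warning.
#' @return state x phase matrix of fractions; rows sum to 1.
#' @export
phase_proportions <- function(phases, states) {
  .assert(length(phases) == length(states), "vectors must be aligned")
  tab <- table(states, phases)
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("dropping empty state(s): ",
            paste(rownames(tab)[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  prop <- sweep(as.matrix(tab), 1, rowSums(tab), "/")
  prop
}
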