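#' Log-normalize an RNA count matrix
#'
#' Per cell, counts are scaled to `scale_factor` total and log-transformed:
#' `x = ln(1 + scale_factor * c / colsum)`.
#'
#' @param counts non-negative gene x cell count matrix.
#' @param scale_factor library-size target (default 10000).
#' @return matrix of the same shape (sparse in, sparse out).
#' @export
normalize_rna <- function(counts, scale_factor = 1e4) {
  tot <- Matrix::colSums(counts)
  if (any(tot == 0))
    stop("cell(s) with zero total counts; filter before normalizing",
         call. = FALSE)
  m <- counts %*% Matrix::Diagonal(x = scale_factor / tot)
  dimnames(m) <- dimnames(counts)
  log1p(m)
}

#' Detection fraction of features
#'
#' Fraction of the selected cells in which each feature has count > 0.
#'
#' @param m feature x cell matrix.
#' @param cells cell index (character, integer or logical); must be non-empty.
#' @param features optional feature subset.
#' @return named numeric vector of fractions.
#' @export
detection_fraction <- function(m, cells, features = NULL) {
  sub <- m[, cells, drop = FALSE]
  .assert(ncol(sub) > 0, "empty cell subset")
  if (!is.null(features)) sub <- sub[features, , drop = FALSE]
  Matrix::rowSums(sub > 0) / ncol(sub)
}

#' Log fold change between two cell groups
#'
#' Computed on back-transformed normalized expression:
#' `ln((mean_a + 1) / (mean_b + 1))` with `mean_g` the group mean of
#' `exp(x) - 1`. Natural log throughout.
#'
#' @param norm normalized gene x cell matrix (output of [normalize_rna()]).
#' @param group_a,group_b disjoint non-empty cell indices.
#' @param features optional feature subset.
#' @return named numeric vector of log fold changes (a vs b).
#' @export
log_fold_change <- function(norm, group_a, group_b, features = NULL) {
  a <- norm[, group_a, drop = FALSE]
  b <- norm[, group_b, drop = FALSE]
  .assert(ncol(a) > 0 && ncol(b) > 0, "groups must be non-empty")
  if (!is.null(features)) {
    a <- a[features, , drop = FALSE]; b <- b[features, , drop = FALSE]
  }
  ma <- Matrix::rowSums(expm1(a)) / ncol(a)
  mb <- Matrix::rowSums(expm1(b)) / ncol(b)
  log((ma + 1) / (mb + 1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in [0,1].
#' @return adjusted p-values, order-preserving to the input.
#' @export
bh_adjust <- function(p) {
  .assert(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must be in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjustment
#'
#' @param p numeric vector of p-values in [0,1].
#' @return `pmin(1, length(p) * p)`.
#' @export
bonferroni_adjust <- function(p) {
  .assert(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must be in [0,1]")
  stats::p.adjust(p, method = "bonferroni")
}

.adjust <- function(p, method = c("BH", "bonferroni")) {
  switch(match.arg(method), BH = bh_adjust(p), bonferroni = bonferroni_adjust(p))
}

# two-sided Wilcoxon rank-sum p for one feature; mid-ranks for ties.
# Exact branch: enumeration of all group-a rank assignments, two-sided p =
# min(1, 2*min(P(W<=w), P(W>=w))). Approximate branch: normal with tie
# correction and 0.5 continuity correction.
.wilcox_p <- function(x, y, exact_max = 20L) {
  na <- length(x); nb <- length(y); N <- na + nb
  r <- rank(c(x, y))
  w <- sum(r[seq_len(na)])
  if (N <= exact_max) {
    combos <- utils::combn(N, na)
    ws <- colSums(matrix(r[combos], nrow = na))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(ws <= w + eps), mean(ws >= w - eps)))
    return(p)
  }
  mu <- na * (N + 1) / 2
  ties <- table(r)
  sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# shared pre-filter on detection fraction and logFC
.de_prefilter <- function(pct_a, pct_b, logfc, min_pct, min_logfc) {
  pmax(pct_a, pct_b) >= min_pct & abs(logfc) >= min_logfc
}

.de_result <- function(feature_id, group_a, group_b, pct_a, pct_b, logfc,
                       p_raw, method = "BH", alpha = 0.05) {
  p_adj <- .adjust(p_raw, method)
  n <- length(feature_id)
  group_a <- rep_len(group_a, n); group_b <- rep_len(group_b, n)
  data.frame(feature_id = feature_id, group_a = group_a, group_b = group_b,
             pct_a = pct_a, pct_b = pct_b, logfc = logfc, p_raw = p_raw,
             p_adj = p_adj, significant = !is.na(p_adj) & p_adj < alpha,
             row.names = NULL)
}

#' Wilcoxon rank-sum differential expression
#'
#' Features are pre-filtered to those detected in at least `min_pct` of one
#' group with `|logfc| >= min_logfc`; only tested features are reported and
#' enter the multiple-testing correction. Exact enumeration is used when the
#' two groups together hold at most `exact_max` cells, otherwise a normal
#' approximation with tie and continuity corrections. A feature constant
#' across both groups gets p = 1.
#'
#' @param norm normalized gene x cell matrix.
#' @param group_a,group_b disjoint cell indices with >= 3 cells each.
#' @param min_pct,min_logfc pre-filter thresholds (defaults 0.10, 0.25).
#' @param method multiple-testing correction, "BH" (default) or "bonferroni".
#' @param alpha significance level on adjusted p (default 0.05).
#' @param exact_max largest combined group size for the exact branch.
#' @param label_a,label_b group labels carried into the result.
#' @return data.frame of per-feature test records (DifferentialResult).
#' @export
wilcoxon_de <- function(norm, group_a, group_b, min_pct = 0.10,
                        min_logfc = 0.25, method = "BH", alpha = 0.05,
                        exact_max = 20L, label_a = "A", label_b = "B") {
  a <- norm[, group_a, drop = FALSE]; b <- norm[, group_b, drop = FALSE]
  .assert(ncol(a) >= 3 && ncol(b) >= 3, "need >= 3 cells per group")
  pct_a <- as.numeric(Matrix::rowSums(a > 0) / ncol(a))
  pct_b <- as.numeric(Matrix::rowSums(b > 0) / ncol(b))
  logfc <- as.numeric(log_fold_change(norm, group_a, group_b))
  keep <- .de_prefilter(pct_a, pct_b, logfc, min_pct, min_logfc)
  feats <- rownames(norm)[keep]
  am <- as.matrix(a[keep, , drop = FALSE])
  bm <- as.matrix(b[keep, , drop = FALSE])
  p_raw <- vapply(seq_along(feats), function(i) {
    xi <- am[i, ]; yi <- bm[i, ]
    if (max(c(xi, yi)) == min(c(xi, yi))) return(1)
    .wilcox_p(xi, yi, exact_max)
  }, numeric(1))
  .de_result(feats, label_a, label_b, pct_a[keep], pct_b[keep], logfc[keep],
             p_raw, method, alpha)
}

# two-sided Fisher exact p by hypergeometric summation: the sum of point
# probabilities not exceeding the observed one (with the customary 1+1e-7
# relative slack against floating-point ties)
.fisher_p2 <- function(x, m, n, k) {
  if (k == 0 || m + n == 0) return(1)
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  d <- stats::dhyper(support, m, n, k)
  min(1, sum(d[d <= d[x - lo + 1] * (1 + 1e-7)]))
}

#' Two-sided Fisher exact p for 2x2 accessibility tables
#'
#' Vectorized over tables: `x_a` of `n_a` cells accessible in group A versus
#' `x_b` of `n_b` in group B. Two-sided by the minimum-likelihood rule (see
#' [fisher_dap()]).
#'
#' @param x_a,n_a,x_b,n_b integer vectors (recycled to a common length).
#' @return numeric vector of p-values.
#' @export
fisher_exact_p <- function(x_a, n_a, x_b, n_b) {
  ln <- max(length(x_a), length(n_a), length(x_b), length(n_b))
  x_a <- rep_len(x_a, ln); n_a <- rep_len(n_a, ln)
  x_b <- rep_len(x_b, ln); n_b <- rep_len(n_b, ln)
  vapply(seq_len(ln), function(i)
    .fisher_p2(x_a[i], m = n_a[i], n = n_b[i], k = x_a[i] + x_b[i]),
    numeric(1))
}

#' Fisher exact differential accessibility
#'
#' Accessibility is binarized as count > 0. Per peak, the 2x2 table of
#' accessible/inaccessible by group is tested with a two-sided Fisher exact
#' test (minimum-likelihood definition: the two-sided p sums the
#' hypergeometric point probabilities of every table, at fixed margins, no
#' more probable than the observed one). The pre-filter mirrors
#' [wilcoxon_de()]: detection fraction >= `min_pct` in one group, and a
#' binary log fold change `ln((pct_a + eps)/(pct_b + eps))` with
#' `eps = 1e-3` of magnitude >= `min_logfc`.
#'
#' @param atac peak x cell count matrix.
#' @param group_a,group_b disjoint non-empty cell indices.
#' @inheritParams wilcoxon_de
#' @param eps detection-fraction pseudocount for the binary logFC.
#' @return data.frame of per-peak test records.
#' @export
fisher_dap <- function(atac, group_a, group_b, min_pct = 0.10,
                       min_logfc = 0.25, eps = 1e-3, method = "BH",
                       alpha = 0.05, label_a = "A", label_b = "B") {
  a <- atac[, group_a, drop = FALSE]; b <- atac[, group_b, drop = FALSE]
  .assert(ncol(a) > 0 && ncol(b) > 0, "empty group")
  na <- ncol(a); nb <- ncol(b)
  xa <- as.integer(Matrix::rowSums(a > 0))
  xb <- as.integer(Matrix::rowSums(b > 0))
  pct_a <- xa / na; pct_b <- xb / nb
  logfc <- log((pct_a + eps) / (pct_b + eps))
  keep <- .de_prefilter(pct_a, pct_b, logfc, min_pct, min_logfc)
  idx <- which(keep)
  p_raw <- vapply(idx, function(i)
    .fisher_p2(xa[i], m = na, n = nb, k = xa[i] + xb[i]), numeric(1))
  .de_result(rownames(atac)[idx], label_a, label_b, pct_a[idx], pct_b[idx],
             logfc[idx], p_raw, method, alpha)
}

# logistic regression by iteratively reweighted least squares with an
# optional ridge penalty; returns coefficients and the log-likelihood
.irls_logistic <- function(X, y, ridge = 0, maxit = 100L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    H <- XtW %*% X + diag(ridge, ncol(X))
    beta_new <- tryCatch(drop(solve(H, XtW %*% z)), error = function(e) NULL)
    if (is.null(beta_new)) return(NULL)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  log1pexp <- function(e) ifelse(e > 30, e, log1p(exp(e)))
  list(beta = beta, loglik = sum(y * eta - log1pexp(eta)))
}

#' Logistic-regression differential accessibility
#'
#' Per peak, a likelihood-ratio test compares
#' `logit(accessible) ~ covariate` against
#' `logit(accessible) ~ group + covariate`, with p from chi-squared on one
#' degree of freedom. The covariate is the per-cell total fragment count in
#' peaks (the standard latent variable for this test). Fitting is IRLS with
#' at most 100 iterations at tolerance 1e-8; on (near) separation the fit is
#' repeated with a ridge penalty of 1e-6 and the record is flagged. The same
#' pre-filters as [fisher_dap()] apply.
#'
#' @inheritParams fisher_dap
#' @param covariate per-cell numeric covariate over all columns of `atac`
#'   (default: column sums, the total fragments in peaks).
#' @return data.frame of per-peak records, with a `flagged` column marking
#'   ridge-stabilized fits.
#' @export
logistic_dap <- function(atac, group_a, group_b, covariate = NULL,
                         min_pct = 0.10, min_logfc = 0.25, eps = 1e-3,
                         method = "BH", alpha = 0.05,
                         label_a = "A", label_b = "B") {
  if (is.null(covariate)) covariate <- Matrix::colSums(atac)
  .assert(all(is.finite(covariate)), "covariate must be finite")
  names(covariate) <- colnames(atac)
  a <- atac[, group_a, drop = FALSE]; b <- atac[, group_b, drop = FALSE]
  .assert(ncol(a) > 0 && ncol(b) > 0, "empty group")
  na <- ncol(a); nb <- ncol(b)
  xa <- as.integer(Matrix::rowSums(a > 0))
  xb <- as.integer(Matrix::rowSums(b > 0))
  pct_a <- xa / na; pct_b <- xb / nb
  logfc <- log((pct_a + eps) / (pct_b + eps))
  keep <- which(.de_prefilter(pct_a, pct_b, logfc, min_pct, min_logfc))

  grp <- c(rep(1, na), rep(0, nb))
  cov <- c(covariate[colnames(a)], covariate[colnames(b)])
  cov_s <- if (stats::sd(cov) > 0) (cov - mean(cov)) / stats::sd(cov) else cov * 0
  X0 <- cbind(1, cov_s)
  X1 <- cbind(1, grp, cov_s)
  amat <- as.matrix(a[keep, , drop = FALSE] > 0)
  bmat <- as.matrix(b[keep, , drop = FALSE] > 0)

  p_raw <- numeric(length(keep)); flagged <- logical(length(keep))
  for (j in seq_along(keep)) {
    y <- as.numeric(c(amat[j, ], bmat[j, ]))
    f0 <- .irls_logistic(X0, y)
    f1 <- .irls_logistic(X1, y)
    sep <- is.null(f0) || is.null(f1) || any(abs(f1$beta) > 15)
    if (sep) {
      f0 <- .irls_logistic(X0, y, ridge = 1e-6)
      f1 <- .irls_logistic(X1, y, ridge = 1e-6)
      flagged[j] <- TRUE
    }
    lrt <- max(0, 2 * (f1$loglik - f0$loglik))
    p_raw[j] <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  out <- .de_result(rownames(atac)[keep], label_a, label_b, pct_a[keep],
                    pct_b[keep], logfc[keep], p_raw, method, alpha)
  out$flagged <- flagged
  out
}

#' Cell-type-specific peaks by all-pairs dominance
#'
#' A peak is specific to type t iff, for every other type u, the pairwise
#' test (Fisher exact by default) marks it significant with a higher
#' detection fraction in t. The resulting sets are disjoint by construction.
#'
#' @param atac peak x cell count matrix.
#' @param labels per-cell type labels aligned to columns.
#' @param test "fisher" (default) or "logistic".
#' @param ... passed to [fisher_dap()] / [logistic_dap()].
#' @return named list: type -> character vector of specific peak ids.
#' @export
celltype_specific_peaks <- function(atac, labels, test = c("fisher", "logistic"),
                                    ...) {
  test <- match.arg(test)
  types <- unique(labels)
  .assert(length(types) >= 2, "need at least two cell types")
  fun <- if (test == "fisher") fisher_dap else logistic_dap
  pairs <- utils::combn(types, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    fun(atac, which(labels == pr[1]), which(labels == pr[2]),
        label_a = pr[1], label_b = pr[2], ...)
  })
  out <- stats::setNames(vector("list", length(types)), types)
  for (t in types) {
    wins <- NULL
    ok <- TRUE
    for (i in seq_along(pairs)) {
      pr <- pairs[[i]]
      if (!(t %in% pr)) next
      r <- res[[i]]
      winners <- if (pr[1] == t)
        r$feature_id[r$significant & r$pct_a > r$pct_b]
      else
        r$feature_id[r$significant & r$pct_b > r$pct_a]
      wins <- if (is.null(wins)) winners else intersect(wins, winners)
    }
    out[[t]] <- sort(if (is.null(wins)) character(0) else wins)
  }
  out
}

#' Accessible peak sets per cell type
#'
#' A peak is accessible in a type when detected (count > 0) in strictly more
#' than `min_pct` of that type's cells.
#'
#' @inheritParams celltype_specific_peaks
#' @param min_pct detection cutoff (default 0.10, strict).
#' @return named list: type -> character vector of peak ids.
#' @export
accessible_peak_sets <- function(atac, labels, min_pct = 0.10) {
  types <- unique(labels)
  stats::setNames(lapply(types, function(t) {
    frac <- detection_fraction(atac, which(labels == t))
    sort(rownames(atac)[frac > min_pct])
  }), types)
}

#' Shared and unique peak counts (upset-style)
#'
#' Counts, for every non-empty subset of types, the peaks belonging to
#' exactly that subset of the given accessible-peak sets.
#'
#' @param sets named list of peak-id character vectors.
#' @return data.frame: `combination` (type names joined by "&"), `degree`,
#'   `count`, covering all non-empty subsets.
#' @export
shared_unique_peaks <- function(sets) {
  types <- names(sets)
  .assert(!is.null(types) && all(nzchar(types)), "sets must be named")
  universe <- unique(unlist(sets))
  member <- sapply(sets, function(s) universe %in% s)
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  key <- apply(member, 1, function(z) paste(types[z], collapse = "&"))
  combos <- unlist(lapply(seq_along(types), function(d)
    utils::combn(types, d, FUN = paste, collapse = "&")))
  counts <- table(factor(key, levels = combos))
  data.frame(combination = combos,
             degree = lengths(strsplit(combos, "&", fixed = TRUE)),
             count = as.integer(counts), row.names = NULL)
}
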