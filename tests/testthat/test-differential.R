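norm_fixture <- function(counts) {
  normalize_rna(Matrix::Matrix(counts, sparse = TRUE))
}

test_that("normalization follows ln(1 + 1e4 * c / total)", {
  m <- matrix(0, nrow = 3, ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  m["g1", "c1"] <- 1; m["g2", "c1"] <- 9999   # total 10000
  m["g1", "c2"] <- 5; m["g2", "c2"] <- 4995   # total 5000
  x <- norm_fixture(m)
  expect_equal(x["g1", "c1"], log(2))
  expect_equal(x["g3", "c1"], 0)
  expect_equal(x["g1", "c2"], log(11))
  m0 <- m; m0[, 2] <- 0
  expect_error(norm_fixture(m0), "zero total")
})

test_that("log fold change is antisymmetric and matches the formula", {
  set.seed(5)
  m <- matrix(rpois(200, 3), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("c%02d", 1:20)))
  x <- norm_fixture(m)
  a <- 1:10; b <- 11:20
  fc <- log_fold_change(x, a, b)
  expect_equal(unname(log_fold_change(x, b, a)), unname(-fc))
  expect_equal(unname(log_fold_change(x, a, a)), rep(0, 10))
  # m_a = e-1, m_b = 0 -> ln(e/1) = 1
  y <- Matrix::Matrix(matrix(c(log(exp(1) - 1 + 1), 0), nrow = 1,
                             dimnames = list("g", c("ca", "cb"))) , sparse = TRUE)
  # construct normalized values directly: exp(x)-1 gives e-1 and 0
  yv <- matrix(c(log(exp(1)), 0), nrow = 1,
               dimnames = list("g", c("ca", "cb")))
  expect_equal(unname(log_fold_change(yv, 1, 2)), 1)
})

test_that("BH and Bonferroni match closed forms and bound properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bonferroni_adjust(c(0.01, 0.02)), c(0.02, 0.04))
  expect_equal(bonferroni_adjust(c(0.9, 0.9)), c(1, 1))
  set.seed(2)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p & q <= 1))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), q[perm])  # permutation equivariance
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("wilcoxon exact branch matches full rank-assignment enumeration", {
  # {1,2,3} vs {4,5,6}: two-sided exact p = 2 * 1/20 = 0.1
  x <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
              dimnames = list("g", sprintf("c%d", 1:6)))
  r <- wilcoxon_de(x, 1:3, 4:6, min_pct = 0, min_logfc = 0)
  expect_equal(r$p_raw, 0.1)
  # identical distributions -> p = 1
  x2 <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 1,
               dimnames = list("g", sprintf("c%d", 1:6)))
  expect_equal(wilcoxon_de(x2, 1:3, 4:6, min_pct = 0, min_logfc = 0)$p_raw, 1)
  # random tied data, n_a + n_b <= 12: oracle enumerates all assignments
  set.seed(31)
  for (rep in 1:5) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    v <- sample(0:3, na + nb, replace = TRUE)
    if (max(v) == min(v)) v[1] <- v[1] + 1
    xr <- matrix(v, nrow = 1, dimnames = list("g", sprintf("c%d", 1:(na + nb))))
    got <- wilcoxon_de(xr, 1:na, na + 1:nb, min_pct = 0, min_logfc = 0)$p_raw
    r_all <- rank(v)
    combos <- combn(na + nb, na)
    ws <- colSums(matrix(r_all[combos], nrow = na))
    w_obs <- sum(r_all[1:na])
    want <- min(1, 2 * min(mean(ws <= w_obs + 1e-9),
                           mean(ws >= w_obs - 1e-9)))
    expect_equal(got, want)
  }
  # tie-free case agrees with stats::wilcox.test exact p
  set.seed(32)
  v <- sample(1:12)
  xr <- matrix(v, nrow = 1, dimnames = list("g", sprintf("c%d", 1:12)))
  got <- wilcoxon_de(xr, 1:6, 7:12, min_pct = 0, min_logfc = 0)$p_raw
  want <- stats::wilcox.test(v[1:6], v[7:12], exact = TRUE)$p.value
  expect_equal(got, want)
})

test_that("wilcoxon approximate branch tracks the exact branch", {
  set.seed(77)
  diffs <- replicate(40, {
    v <- c(rnorm(10), rnorm(10, 0.8))
    x <- matrix(v, nrow = 1, dimnames = list("g", sprintf("c%d", 1:20)))
    pe <- wilcoxon_de(x, 1:10, 11:20, min_pct = 0, min_logfc = 0,
                      exact_max = 20)$p_raw
    pa <- wilcoxon_de(x, 1:10, 11:20, min_pct = 0, min_logfc = 0,
                      exact_max = 0)$p_raw
    abs(pe - pa)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("the 10% / 0.25-logFC pre-filter excludes features before testing", {
  set.seed(8)
  m <- matrix(0, nrow = 2, ncol = 40,
              dimnames = list(c("rare", "flat"), sprintf("c%02d", 1:40)))
  m["rare", c(1, 21)] <- 1          # 5% detection in both groups
  m["flat", ] <- 5                  # detected everywhere, logFC 0
  x <- norm_fixture(m)
  r <- wilcoxon_de(x, 1:20, 21:40)
  expect_false("rare" %in% r$feature_id)
  expect_false("flat" %in% r$feature_id)
})

test_that("fisher p matches hypergeometric enumeration and is symmetric", {
  mk_atac <- function(xa, na, xb, nb) {
    m <- matrix(0, nrow = 1, ncol = na + nb,
                dimnames = list("p1", sprintf("c%d", 1:(na + nb))))
    if (xa > 0) m[1, seq_len(xa)] <- 1
    if (xb > 0) m[1, na + seq_len(xb)] <- 1
    Matrix::Matrix(m, sparse = TRUE)
  }
  # identical tables -> p = 1
  r <- fisher_dap(mk_atac(5, 10, 5, 10), 1:10, 11:20,
                  min_pct = 0, min_logfc = 0)
  expect_equal(r$p_raw, 1)
  # 8/10 vs 2/10: full enumeration of the 11 tables with fixed margins
  r2 <- fisher_dap(mk_atac(8, 10, 2, 10), 1:10, 11:20,
                   min_pct = 0, min_logfc = 0)
  d <- dhyper(0:10, 10, 10, 10)
  want <- sum(d[d <= d[9] * (1 + 1e-7)])
  expect_equal(r2$p_raw, want, tolerance = 1e-12)
  expect_equal(r2$p_raw, fisher.test(matrix(c(8, 2, 2, 8), 2))$p.value,
               tolerance = 1e-9)
  # swapping group labels leaves the two-sided p unchanged
  r3 <- fisher_dap(mk_atac(2, 10, 8, 10), 1:10, 11:20,
                   min_pct = 0, min_logfc = 0)
  expect_equal(r3$p_raw, r2$p_raw)
})

test_that("logistic LRT equals twice the log-likelihood gap and matches glm", {
  set.seed(12)
  n <- 120
  grp <- rep(c(1, 0), each = n / 2)
  cov <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * grp + 0.4 * cov))
  m <- Matrix::Matrix(matrix(y, nrow = 1,
                             dimnames = list("p1", sprintf("c%d", 1:n))),
                      sparse = TRUE)
  r <- logistic_dap(m, 1:(n / 2), (n / 2 + 1):n, covariate = cov,
                    min_pct = 0, min_logfc = 0)
  cov_s <- (cov - mean(cov)) / sd(cov)
  f1 <- glm(y ~ grp + cov_s, family = binomial)
  f0 <- glm(y ~ cov_s, family = binomial)
  lrt <- 2 * (logLik(f1) - logLik(f0))
  expect_equal(r$p_raw, pchisq(as.numeric(lrt), 1, lower.tail = FALSE),
               tolerance = 1e-6)
  # null case: group independent of accessibility, constant covariate
  y0 <- rbinom(n, 1, 0.4)
  m0 <- Matrix::Matrix(matrix(y0, nrow = 1,
                              dimnames = list("p1", sprintf("c%d", 1:n))),
                       sparse = TRUE)
  r0 <- logistic_dap(m0, 1:(n / 2), (n / 2 + 1):n, covariate = rep(1, n),
                     min_pct = 0, min_logfc = 0)
  expect_gt(r0$p_raw, 0.01)
})

test_that("perfect separation falls back to a flagged ridge fit", {
  n <- 40
  y <- rep(c(1, 0), each = n / 2)  # accessibility identical to group
  m <- Matrix::Matrix(matrix(y, nrow = 1,
                             dimnames = list("p1", sprintf("c%d", 1:n))),
                      sparse = TRUE)
  r <- logistic_dap(m, 1:(n / 2), (n / 2 + 1):n, covariate = rep(1, n),
                    min_pct = 0, min_logfc = 0)
  expect_true(r$flagged)
  expect_lt(r$p_raw, 1e-6)
})

test_that("type-specific peaks follow all-pairs dominance and recover truth", {
  d <- small_dataset()
  sim <- d$sim
  singlets <- !sim$cells$doublet
  atac <- sim$atac[, singlets]
  labels <- sim$cells$cell_type[singlets]
  spec <- celltype_specific_peaks(atac, labels)
  # disjoint sets
  expect_false(any(duplicated(unlist(spec))))
  # recovery of planted peaks with few misassignments
  truth <- sim$truth$type_specific_peaks
  rec <- mean(unlist(lapply(names(truth), function(t)
    truth[[t]] %in% spec[[t]])))
  expect_gt(rec, 0.8)
  planted_all <- unlist(truth)
  false_assign <- setdiff(unlist(spec), planted_all)
  expect_lt(length(false_assign) / max(1, length(unlist(spec))), 0.05)
})

test_that("a peak winning one pairwise test but not the other is not specific", {
  set.seed(21)
  n <- 60
  labels <- rep(c("A", "B", "C"), each = n)
  # peak open in A and B equally, closed in C: beats C but not B
  y <- c(rbinom(n, 1, 0.6), rbinom(n, 1, 0.6), rbinom(n, 1, 0.05))
  m <- Matrix::Matrix(matrix(y, nrow = 1,
                             dimnames = list("p1", sprintf("c%d", 1:(3 * n)))),
                      sparse = TRUE)
  spec <- celltype_specific_peaks(m, labels)
  expect_false("p1" %in% spec$A)
  expect_false("p1" %in% spec$B)
})

test_that("shared/unique peak accounting enumerates exclusive intersections", {
  out <- shared_unique_peaks(list(A = c("p1", "p2"), B = c("p2", "p3"),
                                  C = "p2"))
  get <- function(combo) out$count[out$combination == combo]
  expect_equal(get("A"), 1)
  expect_equal(get("B"), 1)
  expect_equal(get("A&B&C"), 1)
  expect_equal(sum(out$count), 3)
  # identical sets: only the all-types class is non-zero
  out2 <- shared_unique_peaks(list(A = "p1", B = "p1"))
  expect_equal(out2$count[out2$combination == "A&B"], 1)
  expect_equal(sum(out2$count), 1)
  # disjoint sets: only singletons
  out3 <- shared_unique_peaks(list(A = "p1", B = "p2"))
  expect_equal(out3$count[out3$degree == 1], c(1, 1))
  expect_equal(sum(out3$count), 2)
})
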