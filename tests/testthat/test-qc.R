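test_that("RNA QC metrics are direct sums over the matrix", {
  m <- Matrix::Matrix(c(3, 0, 1,   # cell1: gA=3, gB=0, gMT=1
                        0, 0, 0,   # cell2: all zero
                        10, 5, 0), # cell3
                      nrow = 3, sparse = TRUE,
                      dimnames = list(c("gA", "gB", "gMT"),
                                      c("c1", "c2", "c3")))
  qc <- compute_rna_qc(m, "gMT")
  expect_equal(qc$n_genes_detected, c(2L, 0L, 2L))
  expect_equal(qc$n_umis, c(4, 0, 15))
  expect_equal(qc$mito_fraction, c(0.25, 0, 0))  # all-zero cell defined as 0
  expect_false(any(qc$doublet_flag))
  expect_error(compute_rna_qc(m, "nope"), "unknown mitochondrial")
})

test_that("the 40,000-transcript doublet flag is strict", {
  m <- Matrix::Matrix(matrix(c(40000, 45000, 39999), nrow = 1), sparse = TRUE,
                      dimnames = list("g1", c("c1", "c2", "c3")))
  qc <- compute_rna_qc(m)
  expect_equal(qc$doublet_flag, c(FALSE, TRUE, FALSE))
})

test_that("RNA filtering applies every rule and the feature floor", {
  set.seed(1)
  n_cells <- 8
  m <- matrix(5L, nrow = 300, ncol = n_cells,
              dimnames = list(c(sprintf("g%03d", 1:299), "gMT"),
                              sprintf("c%d", 1:n_cells)))
  m["gMT", ] <- 0L
  m[, 2] <- 0L; m[1:150, 2] <- 1L              # 150 genes < 200 -> removed
  m[, 3] <- 25L; m["g001", 3] <- 23800L        # ~31k UMIs -> removed
  m["gMT", 4] <- round(0.12 / 0.88 * sum(m[-300, 4]))  # 12% mito -> removed
  # feature floor: gX detected only in cells 2 and 3 (both removed) + 3 survivors
  m <- rbind(m, gX = 0L)
  m["gX", c(1, 5, 6)] <- 2L
  m <- Matrix::Matrix(m, sparse = TRUE)
  qc <- compute_rna_qc(m, "gMT")
  out <- filter_rna(m, qc)
  expect_false(any(c("c2", "c3", "c4") %in% colnames(out$matrix)))
  expect_equal(ncol(out$matrix), n_cells - 3)
  expect_true("gX" %in% rownames(out$matrix))  # exactly 3 survivors: retained
  expect_false("gMT" %in% rownames(out$matrix))
  expect_equal(unname(out$report["cells_removed"]), 3)
  # idempotence: filtering the filtered matrix removes nothing
  qc2 <- compute_rna_qc(out$matrix, character(0))
  out2 <- filter_rna(out$matrix, qc2, min_genes = 0)
  expect_identical(dim(out2$matrix), dim(out$matrix))
})

test_that("nucleosome signal and FRiP match hand counts", {
  frag <- data.frame(
    chrom = "chr1",
    start = c(rep(5000, 60), rep(8000, 30)),
    end = c(rep(5000, 60) + 100, rep(8000, 30) + 180),
    barcode = "cellA", count = 1L)
  ann <- toy_annotation()
  pk <- peak_row("chr1", 4900, 5200)  # covers the 60 length-100 fragments
  qc <- compute_atac_qc(frag, pk, ann)
  expect_equal(qc$nucleosome_signal, 30 / 60)
  expect_equal(qc$frip, 60 / 90)
  expect_equal(qc$n_fragments, 90L)
})

test_that("uniform genome-wide insertions give TSS enrichment near 1", {
  set.seed(99)
  ann <- toy_annotation()
  n <- 40000
  start <- sample.int(9e4, n, replace = TRUE)
  frag <- data.frame(chrom = "chr1", start = start, end = start + 100,
                     barcode = "u1", count = 1L)
  qc <- compute_atac_qc(frag, peak_row("chr1", 0, 10), ann)
  expect_lt(abs(qc$tss_enrichment - 1), 0.25)
})

test_that("zero-fragment barcodes get zero metrics, not errors", {
  frag <- data.frame(chrom = "chr1", start = 100, end = 250,
                     barcode = "present", count = 1L)
  qc <- compute_atac_qc(frag, peak_row("chr1", 0, 10), toy_annotation(),
                        barcodes = c("present", "absent"))
  z <- qc[qc$barcode == "absent", ]
  expect_equal(z$n_fragments, 0L)
  expect_equal(z$tss_enrichment, 0)
  expect_equal(z$frip, 0)
})

test_that("ATAC filter enforces every boundary as documented", {
  mk <- function(n_fragments = 5000, mito_ratio = 0.01, tss_enrichment = 10,
                 nucleosome_signal = 1, frip = 0.8) {
    data.frame(n_fragments = n_fragments, mito_ratio = mito_ratio,
               tss_enrichment = tss_enrichment,
               nucleosome_signal = nucleosome_signal, frip = frip)
  }
  qc <- do.call(rbind, list(
    mk(),                              # keep
    mk(n_fragments = 1500),            # below 2000
    mk(n_fragments = 2000),            # boundary: kept (inclusive)
    mk(n_fragments = 30000),           # boundary: kept (inclusive)
    mk(n_fragments = 30001),           # above
    mk(mito_ratio = 0.02),             # boundary: removed (strict <)
    mk(tss_enrichment = 2),            # boundary: removed (strict >)
    mk(tss_enrichment = 50),           # above 40
    mk(nucleosome_signal = 5),         # boundary: removed (strict <)
    mk(frip = 0.50)))                  # boundary: removed (strict >)
  qc$barcode <- sprintf("c%02d", seq_len(nrow(qc)))
  m <- Matrix::Matrix(matrix(1, nrow = 2, ncol = nrow(qc),
                             dimnames = list(c("p1", "p2"), qc$barcode)),
                      sparse = TRUE)
  out <- filter_atac(m, qc)
  expect_setequal(colnames(out$matrix), c("c01", "c03", "c04"))
  # oracle: independent per-cell rule evaluation
  keep <- with(qc, n_fragments >= 2000 & n_fragments <= 30000 &
                 mito_ratio < 0.02 & tss_enrichment > 2 & tss_enrichment < 40 &
                 nucleosome_signal < 5 & frip > 0.5)
  expect_identical(colnames(out$matrix), qc$barcode[keep])
})

test_that("mito fraction and FRiP are invariant under column permutation", {
  d <- small_dataset()
  rna <- d$sim$rna
  mito <- grep("^MT-", rownames(rna), value = TRUE)
  qc1 <- compute_rna_qc(rna, mito)
  perm <- sample(ncol(rna))
  qc2 <- compute_rna_qc(rna[, perm], mito)
  expect_equal(qc2$mito_fraction, qc1$mito_fraction[perm])
})
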