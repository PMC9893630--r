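test_that("promoters are strand-aware, 2 kb, clipped at zero", {
  gp <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                   start = 10000, end = 20000, tss = 10000)
  expect_equal(promoter_of(gp), c(8000, 10000))
  gp$tss <- 500; gp$start <- 500
  expect_equal(promoter_of(gp), c(0, 500))
  gm <- data.frame(gene_id = "g", chrom = "chr1", strand = "-",
                   start = 2000, end = 10001, tss = 10000)
  expect_equal(promoter_of(gm), c(10001, 12001))
})

test_that("classification follows the exon-first priority order", {
  ann <- toy_annotation()
  # straddles geneA promoter and first exon (CDS part beyond the UTR) -> exon
  expect_equal(classify_peak(peak_row("chr1", 900, 1300), ann), "exon")
  # only the promoter (ends exactly at the TSS, half-open) -> promoter
  expect_equal(classify_peak(peak_row("chr1", 200, 1000), ann), "promoter")
  # promoter + 5'-UTR but no CDS exon: promoter outranks utr5
  expect_equal(classify_peak(peak_row("chr1", 900, 1150), ann), "promoter")
  # 5'-UTR + intron only (UTR ends at 1200, CDS starts at 1200): utr5 wins
  # over intron; place inside [1000,1200) is pure UTR -> need no promoter
  expect_equal(classify_peak(peak_row("chr1", 1190, 1210), ann),
               "exon")  # touches CDS [1200,1500)
  # purely inside the 5'-UTR -> utr5
  expect_equal(classify_peak(peak_row("chr1", 1050, 1150), ann), "utr5")
  # intron only
  expect_equal(classify_peak(peak_row("chr1", 2000, 2500), ann), "intron")
  # 3'-UTR + downstream intergenic -> utr3
  expect_equal(classify_peak(peak_row("chr1", 5900, 6500), ann), "utr3")
  # nothing -> distal
  expect_equal(classify_peak(peak_row("chr1", 50000, 50500), ann), "distal")
  # minus-strand gene: promoter upstream is to the right of the TSS
  expect_equal(classify_peak(peak_row("chr1", 26500, 27000), ann), "promoter")
  # minus-strand 5'-UTR at the right end of the gene
  expect_equal(classify_peak(peak_row("chr1", 25800, 25900), ann), "utr5")
  expect_error(classify_peak(peak_row("chrZ", 0, 100), ann), "unknown contig")
})

test_that("adding a lower-priority overlap never changes a label", {
  ann <- toy_annotation()
  # exon peak also spanning intron and utr3 still reads exon
  expect_equal(classify_peak(peak_row("chr1", 1300, 5600), ann), "exon")
  # promoter peak extended into distal space still reads promoter
  expect_equal(classify_peak(peak_row("chr1", 100, 900), ann), "promoter")
})

test_that("classification agrees with the brute-force oracle on random genomes", {
  for (seed in c(101, 202, 303, 404, 505)) {
    toy <- random_toy_genome(seed)
    set.seed(seed + 1)
    n <- 200
    w <- sample(100:2000, n, replace = TRUE)
    s <- sample.int(max(toy$annotation$genes$end) + 10000, n)
    pk <- data.frame(peak_id = sprintf("p%03d", seq_len(n)), chrom = "chr1",
                     start = s, end = s + w)
    got <- classify_peaks(pk, toy$annotation)
    want <- brute_classify(pk, toy$annotation)
    expect_identical(unname(got), want)
  }
})

test_that("stratification filters at a strict 10% and sums to 100", {
  ann <- toy_annotation()
  pk <- rbind(peak_row("chr1", 1300, 1400),    # exon
              peak_row("chr1", 300, 700),      # promoter
              peak_row("chr1", 2000, 2400),    # intron
              peak_row("chr1", 50000, 50400),  # distal
              peak_row("chr1", 60000, 60400))  # distal, detected in 10% only
  cells <- sprintf("c%02d", 1:20)
  m <- matrix(1, nrow = 5, ncol = 20, dimnames = list(pk$peak_id, cells))
  m[5, ] <- 0; m[5, 1:2] <- 1                  # exactly 10%: excluded
  m <- Matrix::Matrix(m, sparse = TRUE)
  out <- stratify_peaks(pk, ann, m, cells)
  expect_equal(sum(out), 100, tolerance = 1e-9)
  expect_equal(unname(out[c("exon", "promoter", "intron", "distal")]),
               c(25, 25, 25, 25))
  expect_error(stratify_peaks(pk, ann, m, character(0)), "empty")
  # hand tally: 3 exon, 2 promoter, 5 distal -> 30/20/50
  pk2 <- rbind(peak_row("chr1", 1250, 1350, "e1"),
               peak_row("chr1", 1350, 1450, "e2"),
               peak_row("chr1", 5400, 5650, "e3"),
               peak_row("chr1", 100, 500, "pr1"),
               peak_row("chr1", 500, 900, "pr2"),
               peak_row("chr1", 40000, 40100, "d1"),
               peak_row("chr1", 41000, 41100, "d2"),
               peak_row("chr1", 42000, 42100, "d3"),
               peak_row("chr1", 43000, 43100, "d4"),
               peak_row("chr1", 44000, 44100, "d5"))
  m2 <- Matrix::Matrix(matrix(1, nrow = 10, ncol = 20,
                              dimnames = list(pk2$peak_id, cells)),
                       sparse = TRUE)
  out2 <- stratify_peaks(pk2, ann, m2, cells)
  expect_equal(unname(out2[c("exon", "promoter", "distal")]), c(30, 20, 50))
})
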