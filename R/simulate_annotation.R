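#' Simulate a gene annotation and peak set
#'
#' Builds a deterministic toy genome on one main chromosome plus a
#' mitochondrial contig: each gene has a strand, TSS, 2-4 exons and
#' 5'/3'-UTR segments; peaks (widths 200-1000 bp) are placed so that every
#' genomic element class (exon, promoter, 5'-UTR, 3'-UTR, intron, distal) is
#' represented, including peaks deliberately straddling two classes so the
#' priority-resolution rule is exercised. All coordinates are 0-based
#' half-open. Genes are laid out in equal non-overlapping slots; an error is
#' raised when the chromosome is too short to hold them.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `annotation` (class `genome_annotation`:
#'   `genes`, `exons`, `utr5`, `utr3` data frames and a named `chroms` length
#'   vector) and `peaks` (data frame `peak_id`, `chrom`, `start`, `end` with a
#'   `target_class` attribute column recording the placement intent).
#' @export
simulate_annotation <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_annotation_impl(config))
}

.simulate_annotation_impl <- function(config) {
  n_genes <- config$n_genes
  L <- config$chrom_length
  chroms <- c(chr1 = L, chrM = 16000)

  genes <- exons <- utr5 <- utr3 <- NULL
  if (n_genes > 0) {
    slot <- floor(L / n_genes)
    if (slot < 30000)
      stop("chromosome too short to place ", n_genes,
           " non-overlapping genes (need >= 30 kb per gene)", call. = FALSE)
    glist <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      k <- sample(2:4, 1)
      ex_len <- round(stats::runif(k, 300, 800))
      in_len <- if (k > 1) round(stats::runif(k - 1, 1500, 4000)) else integer(0)
      body_len <- sum(ex_len) + sum(in_len)
      slot_start <- (i - 1) * slot
      gstart <- slot_start + round(stats::runif(1, 3000, slot - body_len - 3000))
      strand <- sample(c("+", "-"), 1)
      # exon coordinates left-to-right
      ex_start <- gstart + cumsum(c(0, head(ex_len, -1) + in_len))
      ex_end <- ex_start + ex_len
      gend <- ex_end[k]
      # about half the genes carry full-UTR terminal exons (the whole first
      # and last exon are UTR); the rest carry partial terminal UTRs
      full_utr <- stats::runif(1) < 0.5
      if (strand == "+") {
        tss <- gstart
        u5_len <- if (full_utr) ex_len[1] else max(50L, round(0.3 * ex_len[1]))
        u3_len <- if (full_utr) ex_len[k] else max(50L, round(0.3 * ex_len[k]))
        u5 <- c(ex_start[1], ex_start[1] + u5_len)
        u3 <- c(ex_end[k] - u3_len, ex_end[k])
      } else {
        tss <- gend - 1
        u5_len <- if (full_utr) ex_len[k] else max(50L, round(0.3 * ex_len[k]))
        u3_len <- if (full_utr) ex_len[1] else max(50L, round(0.3 * ex_len[1]))
        u5 <- c(ex_end[k] - u5_len, ex_end[k])
        u3 <- c(ex_start[1], ex_start[1] + u3_len)
      }
      gid <- sprintf("gene%04d", i)
      glist[[i]] <- list(
        gene = data.frame(gene_id = gid, chrom = "chr1", strand = strand,
                          start = gstart, end = gend, tss = tss),
        exons = data.frame(gene_id = gid, chrom = "chr1",
                           start = ex_start, end = ex_end),
        utr5 = data.frame(gene_id = gid, chrom = "chr1",
                          start = u5[1], end = u5[2]),
        utr3 = data.frame(gene_id = gid, chrom = "chr1",
                          start = u3[1], end = u3[2]))
    }
    genes <- do.call(rbind, lapply(glist, `[[`, "gene"))
    exons <- do.call(rbind, lapply(glist, `[[`, "exons"))
    utr5 <- do.call(rbind, lapply(glist, `[[`, "utr5"))
    utr3 <- do.call(rbind, lapply(glist, `[[`, "utr3"))
  } else {
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        strand = character(0), start = numeric(0),
                        end = numeric(0), tss = numeric(0))
    exons <- utr5 <- utr3 <- data.frame(gene_id = character(0),
                                        chrom = character(0),
                                        start = numeric(0), end = numeric(0))
  }

  # mitochondrial genes: single-exon, no UTR annotation
  n_mito <- 5L
  mt_start <- seq(500, by = 3000, length.out = n_mito)
  mt <- data.frame(gene_id = paste0("MT-gene", seq_len(n_mito)), chrom = "chrM",
                   strand = "+", start = mt_start, end = mt_start + 1000,
                   tss = mt_start)
  genes <- rbind(genes, mt)
  exons <- rbind(exons, data.frame(gene_id = mt$gene_id, chrom = "chrM",
                                   start = mt$start, end = mt$end))

  annotation <- structure(list(genes = genes, exons = exons, utr5 = utr5,
                               utr3 = utr3, chroms = chroms),
                          class = "genome_annotation")

  peaks <- .place_peaks(config, annotation)
  list(annotation = annotation, peaks = peaks)
}

# sample peak placements targeting each element class; the realised class can
# be higher priority when a peak straddles two classes, which is intended
.place_peaks <- function(config, annotation) {
  n_peaks <- config$n_peaks
  genes <- annotation$genes[annotation$genes$chrom == "chr1", , drop = FALSE]
  if (nrow(genes) == 0) {
    w <- round(stats::runif(n_peaks, 200, 1000))
    s <- round(stats::runif(n_peaks, 0, config$chrom_length - w - 1))
    pk <- data.frame(chrom = "chr1", start = s, end = s + w,
                     target_class = "distal", stringsAsFactors = FALSE)
    return(.finish_peaks(pk))
  }
  probs <- c(exon = 0.17, promoter = 0.14, utr5 = 0.07, utr3 = 0.07,
             intron = 0.18, distal = 0.26, straddle = 0.07, tss = 0.04)
  target <- sample(names(probs), n_peaks, replace = TRUE, prob = probs)
  ex_by_gene <- split(annotation$exons[annotation$exons$chrom == "chr1", ],
                      annotation$exons$gene_id[annotation$exons$chrom == "chr1"])
  rows <- vector("list", n_peaks)
  for (i in seq_len(n_peaks)) {
    g <- genes[sample.int(nrow(genes), 1), ]
    ex <- ex_by_gene[[g$gene_id]]
    k <- nrow(ex)
    w <- round(stats::runif(1, 200, 1000))
    plus <- g$strand == "+"
    u5 <- annotation$utr5[annotation$utr5$gene_id == g$gene_id, ]
    u3 <- annotation$utr3[annotation$utr3$gene_id == g$gene_id, ]
    cls <- target[i]
    pos <- switch(cls,
      exon = {
        # overlap the CDS-bearing part of an interior-ish exon
        j <- if (plus) min(2L, k) else max(1L, k - 1L)
        c0 <- max(ex$start[j], u5$end * (j == 1 && plus))
        mid <- floor((ex$start[j] + ex$end[j]) / 2)
        c(mid - floor(w / 2), mid - floor(w / 2) + w)
      },
      promoter = {
        if (plus) {
          e <- g$tss - sample(10:200, 1)
          c(e - w, e)
        } else {
          s <- g$tss + 1 + sample(10:200, 1)
          c(s, s + w)
        }
      },
      utr5 = {
        # sit on the 5'-UTR, spilling into the first intron only
        if (plus) {
          s <- u5$start + sample(0:50, 1)
          e <- min(s + w, if (k > 1) ex$start[2] - 50 else g$end)
          c(s, e)
        } else {
          e <- u5$end - sample(0:50, 1)
          s <- max(e - w, if (k > 1) ex$end[k - 1] + 50 else g$start)
          c(s, e)
        }
      },
      utr3 = {
        if (plus) {
          e <- u3$end - sample(0:50, 1)
          s <- max(e - w, if (k > 1) ex$end[k - 1] + 50 else g$start)
          c(s, e)
        } else {
          s <- u3$start + sample(0:50, 1)
          e <- min(s + w, if (k > 1) ex$start[2] - 50 else g$end)
          c(s, e)
        }
      },
      intron = {
        if (k > 1) {
          j <- sample.int(k - 1, 1)
          s <- ex$end[j] + sample(100:300, 1)
          c(s, min(s + w, ex$start[j + 1] - 50))
        } else c(g$end + 3000, g$end + 3000 + w)  # no intron: falls to distal
      },
      distal = {
        s <- g$end + round(stats::runif(1, 3000, 8000))
        c(s, s + w)
      },
      straddle = {
        # across an exon/intron boundary: exercises exon-over-intron priority
        j <- if (k > 1) sample.int(k - 1, 1) else 1L
        b <- ex$end[j]
        c(b - floor(w / 2), b - floor(w / 2) + w)
      },
      tss = {
        # spanning the TSS: direct cis-link material
        c(g$tss - floor(w / 2), g$tss - floor(w / 2) + w)
      })
    rows[[i]] <- data.frame(chrom = "chr1", start = pos[1], end = pos[2],
                            target_class = cls, stringsAsFactors = FALSE)
  }
  pk <- do.call(rbind, rows)
  pk <- pk[pk$end - pk$start >= 50, , drop = FALSE]
  .finish_peaks(pk)
}

.finish_peaks <- function(pk) {
  pk$start <- pmax(0, pk$start)
  pk <- pk[order(pk$chrom, pk$start, pk$end), , drop = FALSE]
  pk <- pk[!duplicated(pk[, c("chrom", "start", "end")]), , drop = FALSE]
  pk$peak_id <- sprintf("%s:%d-%d", pk$chrom, pk$start, pk$end)
  rownames(pk) <- NULL
  pk[, c("peak_id", "chrom", "start", "end", "target_class")]
}
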