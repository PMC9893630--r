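#' Read and write standard single-cell file formats
#'
#' Matrices travel as MatrixMarket MTX with features.tsv / barcodes.tsv
#' sidecars; peaks as BED (0-based half-open, native); fragments as the
#' 10x-style TSV dialect (chrom, start, end, barcode, count; 0-based
#' half-open, plain or gzip); gene annotation as GTF (1-based closed on
#' disk, converted to 0-based half-open on read); ground truth as JSON.
#'
#' @name multiome-io
NULL

#' Write a feature x cell matrix as an MTX triplet directory
#'
#' @param m sparse feature x cell matrix with dimnames.
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_mtx_dir <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(.as_sparse(m), file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read an MTX triplet directory
#'
#' @param dir directory holding `matrix.mtx`, `features.tsv`, `barcodes.tsv`.
#' @return sparse dgCMatrix with dimnames.
#' @export
read_mtx_dir <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  dimnames(m) <- list(readLines(file.path(dir, "features.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  .as_sparse(m)
}

#' Write peaks as BED
#'
#' @param peaks peak data frame (peak_id, chrom, start, end).
#' @param path output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  data.table::fwrite(peaks[, c("chrom", "start", "end", "peak_id")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read peaks from BED
#'
#' @param path BED file (first four columns chrom, start, end, name; a
#'   missing name column is synthesized as "chrom:start-end").
#' @return peak data frame (peak_id, chrom, start, end).
#' @export
read_peaks_bed <- function(path) {
  b <- data.table::fread(path, header = FALSE)
  pk <- data.frame(chrom = as.character(b[[1]]), start = as.numeric(b[[2]]),
                   end = as.numeric(b[[3]]))
  pk$peak_id <- if (ncol(b) >= 4) as.character(b[[4]])
                else sprintf("%s:%d-%d", pk$chrom, pk$start, pk$end)
  pk[, c("peak_id", "chrom", "start", "end")]
}

#' Write fragment records as a 10x-style TSV
#'
#' @param fragments data frame/table: chrom, start, end, barcode, count.
#' @param path output path (".gz" suffix triggers gzip).
#' @export
write_fragments <- function(fragments, path) {
  data.table::fwrite(fragments, path, sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read a fragments TSV
#'
#' @param path fragments file (plain or gzip), no header.
#' @return data.table: chrom, start, end, barcode, count.
#' @export
read_fragments <- function(path) {
  cols <- c("chrom", "start", "end", "barcode", "count")
  if (grepl("\\.gz$", path)) {
    f <- utils::read.delim(gzfile(path), header = FALSE, col.names = cols)
    return(data.table::as.data.table(f))
  }
  data.table::fread(path, header = FALSE, col.names = cols)
}

#' Write a genome annotation as GTF
#'
#' Emits gene, exon, five_prime_utr and three_prime_utr records; coordinates
#' are converted from the internal 0-based half-open convention to GTF's
#' 1-based closed.
#'
#' @param annotation a `genome_annotation`.
#' @param path output path.
#' @export
write_annotation_gtf <- function(annotation, path) {
  row_of <- function(df, feature) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    data.frame(chrom = df$chrom, source = "sim", feature = feature,
               start = df$start + 1, end = df$end, score = ".",
               strand = annotation$genes$strand[
                 match(df$gene_id, annotation$genes$gene_id)],
               frame = ".",
               attr = sprintf('gene_id "%s";', df$gene_id))
  }
  g <- annotation$genes
  g$gene_id <- g$gene_id
  rows <- rbind(row_of(g, "gene"), row_of(annotation$exons, "exon"),
                row_of(annotation$utr5, "five_prime_utr"),
                row_of(annotation$utr3, "three_prime_utr"))
  rows <- rows[order(rows$chrom, rows$start), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome annotation from GTF
#'
#' Parses gene, exon, five_prime_utr and three_prime_utr records into the
#' internal 0-based half-open representation. The TSS is the gene start on
#' `+` and `end - 1` on `-`. Contig lengths are taken as the maximum end per
#' contig unless supplied.
#'
#' @param path GTF file.
#' @param chrom_lengths optional named vector of contig lengths.
#' @return a `genome_annotation`.
#' @export
read_annotation_gtf <- function(path, chrom_lengths = NULL) {
  g <- data.table::fread(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "source", "feature", "start",
                                       "end", "score", "strand", "frame",
                                       "attr"))
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", g$attr)
  conv <- function(feat, with_strand = FALSE) {
    rows <- which(g$feature == feat)
    d <- g[rows, ]
    out <- data.frame(gene_id = gid[rows],
                      chrom = as.character(d$chrom),
                      start = d$start - 1, end = as.numeric(d$end))
    if (with_strand) out$strand <- as.character(d$strand)
    out
  }
  genes <- conv("gene", with_strand = TRUE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes <- genes[, c("gene_id", "chrom", "strand", "start", "end", "tss")]
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(genes$end, genes$chrom, max) + 1e6
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
  }
  structure(list(genes = genes, exons = conv("exon"),
                 utr5 = conv("five_prime_utr"), utr3 = conv("three_prime_utr"),
                 chroms = chrom_lengths),
            class = "genome_annotation")
}

#' Write a full simulated multiome to a directory
#'
#' Writes RNA and ATAC MTX directories, the peaks BED, the annotation GTF,
#' the fragments TSV (when present), the per-cell table and the planted
#' truth JSON.
#'
#' @param sim output of [simulate_multiome()].
#' @param annotation a `genome_annotation`.
#' @param peaks peak data frame.
#' @param dir output directory.
#' @export
write_multiome <- function(sim, annotation, peaks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mtx_dir(sim$rna, file.path(dir, "rna"))
  write_mtx_dir(sim$atac, file.path(dir, "atac"))
  write_peaks_bed(peaks, file.path(dir, "peaks.bed"))
  write_annotation_gtf(annotation, file.path(dir, "annotation.gtf"))
  if (!is.null(sim$fragments))
    write_fragments(sim$fragments, file.path(dir, "fragments.tsv"))
  data.table::fwrite(sim$cells, file.path(dir, "cells.tsv"), sep = "\t")
  truth <- sim$truth
  truth$motif_in_peak <- NULL  # stored separately as TSV
  occ <- sim$truth$motif_in_peak
  occ_df <- data.frame(motif_id = rownames(occ)[row(occ)[occ]],
                       peak_id = colnames(occ)[col(occ)[occ]])
  data.table::fwrite(occ_df, file.path(dir, "motif_occurrences.tsv"),
                     sep = "\t")
  jsonlite::write_json(lapply(unclass(truth), function(x)
    if (is.data.frame(x)) x else as.list(x)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
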