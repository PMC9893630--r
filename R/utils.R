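#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that generator calls are
#' deterministic without disturbing the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 0-based half-open intervals -> IRanges (1-based closed)
.ir <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# GRanges from 0-based half-open coordinates
.gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(seqnames = chrom, ranges = .ir(start, end))
}

# overlap helpers that first harmonize seqlevels (two GRanges built from
# different contig subsets otherwise warn)
.harmonize <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

.count_overlaps <- function(a, b, minoverlap = 1L) {
  h <- .harmonize(a, b)
  GenomicRanges::countOverlaps(h[[1]], h[[2]], minoverlap = minoverlap)
}

.find_overlaps <- function(a, b, minoverlap = 1L) {
  h <- .harmonize(a, b)
  GenomicRanges::findOverlaps(h[[1]], h[[2]], minoverlap = minoverlap)
}

# data.table subsetting semantics inside the package namespace
.datatable.aware <- TRUE

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# coerce to column-sparse count matrix with dimnames
.as_sparse <- function(m) {
  if (is.matrix(m)) return(Matrix::Matrix(m, sparse = TRUE))
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}
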