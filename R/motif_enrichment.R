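#' Motif enrichment z-scores for a specific peak set
#'
#' For each motif, with n the number of specific peaks, x the number of
#' specific peaks containing the motif and p0 the motif's frequency in the
#' background peak set, the modified z-score is the continuity-corrected
#' binomial deviation
#' `z = (x - n*p0 - 0.5*sign(x - n*p0)) / sqrt(n*p0*(1 - p0))`.
#' Motifs with background frequency exactly 0 or 1 are skipped (z = NA) with
#' a warning. When `gc` is supplied and `gc_match = TRUE`, the background is
#' resampled (with replacement) to match the specific set's GC-content
#' decile composition before computing p0.
#'
#' @param specific_peaks character vector of specific peak ids.
#' @param background_peaks character vector of background peak ids (the peak
#'   universe or a disjoint background).
#' @param occ motif occurrence table: either a logical motif x peak matrix
#'   with dimnames, or a data frame with columns `motif_id`, `peak_id` (one
#'   row per present pair).
#' @param gc optional named per-peak GC-content vector (values in [0,1]).
#' @param gc_match resample the background to match GC deciles.
#' @return named numeric vector of z-scores (one per motif; NA for skipped
#'   motifs), sorted in the occurrence table's motif order.
#' @export
motif_zscore <- function(specific_peaks, background_peaks, occ,
                         gc = NULL, gc_match = FALSE) {
  occm <- .occ_matrix(occ)
  # peaks absent from a long-format occurrence table carry no motifs
  extra <- setdiff(c(specific_peaks, background_peaks), colnames(occm))
  if (length(extra)) {
    occm <- cbind(occm, matrix(FALSE, nrow(occm), length(extra),
                               dimnames = list(rownames(occm), extra)))
  }
  if (gc_match) {
    .assert(!is.null(gc), "gc_match requires per-peak gc values")
    br <- .gc_match_background(specific_peaks, background_peaks, gc)
  } else br <- background_peaks
  n <- length(specific_peaks)
  x <- rowSums(occm[, specific_peaks, drop = FALSE])
  p0 <- rowMeans(occm[, br, drop = FALSE])
  bad <- p0 <= 0 | p0 >= 1
  if (any(bad))
    warning("skipping motif(s) with degenerate background frequency: ",
            paste(rownames(occm)[bad], collapse = ", "))
  dev <- x - n * p0
  s <- ifelse(dev >= 0, 1, -1)  # continuity correction; s = +1 at the null
  z <- (dev - 0.5 * s) / sqrt(n * p0 * (1 - p0))
  z[bad] <- NA_real_
  stats::setNames(as.numeric(z), rownames(occm))
}

.occ_matrix <- function(occ) {
  if (is.matrix(occ)) {
    .assert(!is.null(rownames(occ)) && !is.null(colnames(occ)),
            "occurrence matrix needs motif rownames and peak colnames")
    return(occ > 0)
  }
  .assert(all(c("motif_id", "peak_id") %in% names(occ)),
          "occurrence table needs motif_id and peak_id columns")
  motifs <- sort(unique(occ$motif_id))
  pk <- sort(unique(occ$peak_id))
  m <- matrix(FALSE, length(motifs), length(pk),
              dimnames = list(motifs, pk))
  m[cbind(match(occ$motif_id, motifs), match(occ$peak_id, pk))] <- TRUE
  m
}

# resample background peaks to match the specific set's GC deciles
.gc_match_background <- function(specific, background, gc) {
  .assert(all(c(specific, background) %in% names(gc)),
          "gc values missing for some peaks")
  brks <- unique(stats::quantile(gc[background], probs = seq(0, 1, 0.1)))
  bin <- function(v) cut(v, breaks = brks, include.lowest = TRUE)
  sb <- bin(gc[specific]); bb <- bin(gc[background])
  want <- table(sb)
  out <- character(0)
  for (lv in names(want)) {
    poolv <- background[!is.na(bb) & bb == lv]
    if (length(poolv) == 0) next
    take <- round(length(background) * want[[lv]] / length(specific))
    out <- c(out, sample(poolv, max(1, take), replace = TRUE))
  }
  if (length(out) == 0) background else out
}
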