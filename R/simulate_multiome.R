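#' Simulate a paired single-cell RNA + ATAC dataset with planted truth
#'
#' Generates a gene x cell RNA count matrix, a peak x cell ATAC fragment
#' count matrix, optional 10x-style fragment records, a per-cell metadata
#' table and a ground-truth object recording everything planted.
#'
#' Cells occupy contiguous pseudotime windows along a linear trajectory, one
#' window per ordered cell type. RNA counts are negative binomial; marker
#' genes of each type carry a multiplicative mean lift shaped by the gene's
#' trend template over pseudotime, so the lift peaks inside the focal type's
#' window. Peak detection is Bernoulli (`accessibility_p_base` background,
#' `accessibility_p_high` for a planted peak in its focal type) with
#' 1+Poisson fragment counts where detected. Mitochondrial genes contribute
#' `mito_frac_mean` of RNA counts on average. Doublet barcodes are sums of
#' two random cells. Fragment lengths follow a sub-nucleosomal /
#' mono-nucleosomal / di-nucleosomal mixture and a tunable share of
#' fragments is centred near TSSs, so TSS enrichment and nucleosome-signal
#' QC statistics are exercised.
#'
#' Planted cis links pair each type's marker genes with that type's specific
#' peaks whenever the peak lies within +/-100 kb of the gene's TSS without
#' containing the TSS. One motif per type is planted in 60% of that type's
#' specific peaks against a 10% background occurrence rate.
#'
#' @param config a [sim_config()].
#' @param annotation,peaks output of [simulate_annotation()].
#' @param with_fragments generate per-fragment records (can be skipped when
#'   only count matrices are needed).
#' @return list with `rna`, `atac` (sparse dgCMatrix), `fragments`
#'   (data.table: chrom, start, end, barcode, count; NULL when skipped),
#'   `cells` (data.frame: barcode, sample, cell_type, pseudotime, doublet)
#'   and `truth` (class `sim_truth`).
#' @export
simulate_multiome <- function(config, annotation, peaks,
                              with_fragments = TRUE) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "genome_annotation"))
  with_seed(config$seed + 1L,
            .simulate_multiome_impl(config, annotation, peaks, with_fragments))
}

.simulate_multiome_impl <- function(config, annotation, peaks, with_fragments) {
  k <- config$n_cell_types
  type_names <- if (k == 4) c("Pax3P", "MyoP", "Myob", "Myoc")
                else paste0("type", seq_len(k))
  n <- k * config$cells_per_type
  cell_type <- rep(type_names, each = config$cells_per_type)
  pseudotime <- stats::runif(n, (rep(seq_len(k), each = config$cells_per_type) - 1) / k,
                             rep(seq_len(k), each = config$cells_per_type) / k)
  barcodes <- sprintf("cell%05d", seq_len(n))

  auto_genes <- annotation$genes$gene_id[annotation$genes$chrom != "chrM"]
  mito_genes <- annotation$genes$gene_id[annotation$genes$chrom == "chrM"]

  # --- planted marker genes and their trend templates -----------------------
  n_mark <- round(config$frac_marker_genes * length(auto_genes))
  pool <- sample(auto_genes)
  type_specific_genes <- stats::setNames(vector("list", k), type_names)
  for (i in seq_len(k)) {
    type_specific_genes[[i]] <- sort(pool[seq_len(n_mark) + (i - 1) * n_mark])
  }
  tpl_argmax <- .template_argmax(config$n_trend_templates)
  type_center <- (seq_len(k) - 0.5) / k
  tpl_type <- vapply(tpl_argmax,
                     function(a) which.min(abs(a - type_center)), 1L)
  templates_of_type <- lapply(seq_len(k), function(i) {
    got <- which(tpl_type == i)
    if (length(got) == 0) which.min(abs(tpl_argmax - type_center[i])) else got
  })
  trend_template_of_gene <- integer(0)
  for (i in seq_len(k)) {
    gs <- type_specific_genes[[i]]
    tt <- rep_len(templates_of_type[[i]], length(gs))
    trend_template_of_gene[gs] <- tt
  }

  # --- RNA counts -----------------------------------------------------------
  tplv <- trend_templates(pseudotime, config$n_trend_templates)
  mu <- matrix(config$rna_mean_base, nrow = length(auto_genes), ncol = n,
               dimnames = list(auto_genes, barcodes))
  for (g in names(trend_template_of_gene)) {
    mu[g, ] <- config$rna_mean_base *
      (1 + (config$marker_fold - 1) * tplv[, trend_template_of_gene[[g]]])
  }
  mito_mu_cell <- config$mito_frac_mean / (1 - config$mito_frac_mean) *
    colSums(mu) / length(mito_genes)
  mu_mt <- matrix(rep(mito_mu_cell, each = length(mito_genes)),
                  nrow = length(mito_genes),
                  dimnames = list(mito_genes, barcodes))
  mu_all <- rbind(mu, mu_mt)
  rna <- matrix(stats::rnbinom(length(mu_all), mu = mu_all,
                               size = config$rna_dispersion),
                nrow = nrow(mu_all), dimnames = dimnames(mu_all))

  # --- planted type-specific peaks ------------------------------------------
  n_spec <- round(config$frac_specific_peaks * nrow(peaks))
  tss <- annotation$genes$tss[match(auto_genes, annotation$genes$gene_id)]
  names(tss) <- auto_genes
  pk_gr <- .gr(peaks$chrom, peaks$start, peaks$end)
  contains_tss <- .count_overlaps(
    pk_gr, .gr("chr1", tss, tss + 1)) > 0
  # peaks at a marker gene itself (gene body + 2 kb upstream, TSS excluded)
  # are preferred so marker loci carry type-specific accessibility, as they
  # do in real data; the remainder comes from the +/-100 kb cis neighbourhood
  gdf <- annotation$genes[match(auto_genes, annotation$genes$gene_id), ]
  plus <- gdf$strand == "+"
  act_ws <- ifelse(plus, pmax(0, gdf$start - 2000), gdf$start)
  act_we <- ifelse(plus, gdf$end, gdf$end + 2000)
  type_specific_peaks <- stats::setNames(vector("list", k), type_names)
  taken <- rep(FALSE, nrow(peaks))
  for (i in seq_len(k)) {
    gi <- match(type_specific_genes[[i]], auto_genes)
    gt <- tss[type_specific_genes[[i]]]
    at_gene <- .count_overlaps(pk_gr,
                               .gr("chr1", act_ws[gi], act_we[gi])) > 0
    win <- .gr("chr1", pmax(0, gt - 1e5), gt + 1e5 + 1)
    near <- .count_overlaps(pk_gr, win) > 0
    cand1 <- which(at_gene & !contains_tss & !taken)
    sel <- if (length(cand1) >= n_spec) sample(cand1, n_spec) else cand1
    taken[sel] <- TRUE
    if (length(sel) < n_spec) {
      cand2 <- which(near & !contains_tss & !taken)
      if (length(cand2) < n_spec - length(sel))
        cand2 <- union(cand2, which(!taken & !contains_tss))
      extra <- sample(cand2, min(n_spec - length(sel), length(cand2)))
      taken[extra] <- TRUE
      sel <- c(sel, extra)
    }
    type_specific_peaks[[i]] <- sort(peaks$peak_id[sel])
  }

  # --- ATAC counts ----------------------------------------------------------
  p <- matrix(config$accessibility_p_base, nrow = nrow(peaks), ncol = n,
              dimnames = list(peaks$peak_id, barcodes))
  for (i in seq_len(k)) {
    p[type_specific_peaks[[i]], cell_type == type_names[i]] <-
      config$accessibility_p_high
  }
  detected <- stats::runif(length(p)) < p
  atac <- matrix(0L, nrow = nrow(p), ncol = ncol(p), dimnames = dimnames(p))
  atac[detected] <- stats::rpois(sum(detected), 0.8) + 1L

  # --- planted cis links ----------------------------------------------------
  links <- vector("list", k)
  for (i in seq_len(k)) {
    gs <- type_specific_genes[[i]]
    ps <- match(type_specific_peaks[[i]], peaks$peak_id)
    gt <- tss[gs]
    hits <- .find_overlaps(
      .gr("chr1", pmax(0, gt - 1e5), gt + 1e5 + 1), pk_gr[ps])
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ok <- !(peaks$start[ps][si] <= gt[qi] & gt[qi] < peaks$end[ps][si])
    links[[i]] <- data.frame(gene_id = gs[qi][ok],
                             peak_id = peaks$peak_id[ps][si][ok],
                             cell_type = type_names[i])
  }
  planted_links <- do.call(rbind, links)

  # --- motif occurrences ----------------------------------------------------
  motif_ids <- sprintf("motif%02d", seq_len(config$n_motifs))
  occ <- matrix(stats::runif(config$n_motifs * nrow(peaks)) < 0.10,
                nrow = config$n_motifs,
                dimnames = list(motif_ids, peaks$peak_id))
  motif_of_type <- stats::setNames(motif_ids[seq_len(min(k, config$n_motifs))],
                                   type_names[seq_len(min(k, config$n_motifs))])
  for (i in seq_along(motif_of_type)) {
    ps <- type_specific_peaks[[names(motif_of_type)[i]]]
    occ[motif_of_type[i], ps] <- stats::runif(length(ps)) < 0.60
  }

  # --- doublets -------------------------------------------------------------
  n_d <- round(config$doublet_frac * n)
  doublet_barcodes <- character(0)
  doublet <- rep(FALSE, n)
  if (n_d > 0) {
    i1 <- sample.int(n, n_d); i2 <- sample.int(n, n_d)
    swap <- i1 == i2
    i2[swap] <- (i2[swap] %% n) + 1L
    doublet_barcodes <- sprintf("doublet%03d", seq_len(n_d))
    rna <- cbind(rna, rna[, i1, drop = FALSE] + rna[, i2, drop = FALSE])
    atac <- cbind(atac, atac[, i1, drop = FALSE] + atac[, i2, drop = FALSE])
    colnames(rna)[n + seq_len(n_d)] <- doublet_barcodes
    colnames(atac)[n + seq_len(n_d)] <- doublet_barcodes
    barcodes <- c(barcodes, doublet_barcodes)
    cell_type <- c(cell_type, cell_type[i1])
    pseudotime <- c(pseudotime, (pseudotime[i1] + pseudotime[i2]) / 2)
    doublet <- c(doublet, rep(TRUE, n_d))
  }

  cells <- data.frame(barcode = barcodes, sample = "sim1",
                      cell_type = cell_type, pseudotime = pseudotime,
                      doublet = doublet)

  fragments <- NULL
  if (with_fragments)
    fragments <- .simulate_fragments(config, annotation, peaks, cells)

  truth <- structure(list(
    type_specific_genes = type_specific_genes,
    type_specific_peaks = type_specific_peaks,
    trend_template_of_gene = trend_template_of_gene,
    planted_links = planted_links,
    motif_in_peak = occ,
    motif_of_type = motif_of_type,
    doublet_barcodes = doublet_barcodes,
    pseudotime_of_cell = stats::setNames(pseudotime, barcodes)),
    class = "sim_truth")

  list(rna = .as_sparse(rna), atac = .as_sparse(atac), fragments = fragments,
       cells = cells, truth = truth)
}

# vectorised fragment generation for all cells at once
.simulate_fragments <- function(config, annotation, peaks, cells) {
  n_cells <- nrow(cells)
  nf <- pmax(200, round(stats::rnorm(n_cells, config$fragments_per_cell,
                                     0.15 * config$fragments_per_cell)))
  nf[cells$doublet] <- 2L * nf[cells$doublet]
  total <- sum(nf)
  barcode <- rep(cells$barcode, nf)

  # fragment lengths: sub-nucleosomal / mono-nucleosomal / di-nucleosomal mix
  comp <- sample(1:3, total, replace = TRUE, prob = c(0.60, 0.35, 0.05))
  len <- integer(total)
  len[comp == 1] <- pmin(146L, pmax(20L, round(stats::rnorm(sum(comp == 1), 75, 25))))
  len[comp == 2] <- pmin(294L, pmax(147L, round(stats::rnorm(sum(comp == 2), 200, 25))))
  len[comp == 3] <- pmin(500L, pmax(295L, round(stats::rnorm(sum(comp == 3), 380, 40))))

  # position categories: mitochondrial, in-peak, TSS-proximal, background
  mito <- stats::runif(total) < config$atac_mito_mean
  u <- stats::runif(total)
  cat <- ifelse(mito, "mito",
         ifelse(u < config$frac_fragments_in_peaks, "peak",
         ifelse(u < config$frac_fragments_in_peaks + config$frac_fragments_tss,
                "tss", "bg")))
  start <- integer(total)
  L <- config$chrom_length

  i <- which(cat == "peak")
  if (length(i)) {
    pk <- sample.int(nrow(peaks), length(i), replace = TRUE)
    lo <- peaks$start[pk]
    hi <- pmax(lo, peaks$end[pk] - len[i])
    start[i] <- lo + floor(stats::runif(length(i)) * (hi - lo + 1))
  }
  i <- which(cat == "tss")
  tssv <- annotation$genes$tss[annotation$genes$chrom == "chr1"]
  if (length(i) && length(tssv)) {
    ctr <- tssv[sample.int(length(tssv), length(i), replace = TRUE)] +
      round(stats::rnorm(length(i), 0, 120))
    start[i] <- pmax(0, round(ctr - len[i] / 2))
  } else if (length(i)) cat[i] <- "bg"
  i <- which(cat == "bg")
  if (length(i)) start[i] <- floor(stats::runif(length(i)) * (L - len[i]))
  i <- which(cat == "mito")
  if (length(i)) start[i] <- floor(stats::runif(length(i)) * (16000 - len[i]))

  frag <- data.table::data.table(
    chrom = ifelse(cat == "mito", "chrM", "chr1"),
    start = start, end = start + len, barcode = barcode, count = 1L)
  data.table::setorder(frag, chrom, start, end)
  frag[]
}

#' Simulate continuous trend profiles from the planted templates
#'
#' Draws genes round-robin from the trend templates and emits a continuous
#' gene x cell expression matrix `template(s) + N(0, noise_sd^2)`, together
#' with the cells' pseudotime. Used to validate pseudotime trend-curve
#' estimation and clustering against known template memberships without
#' count noise on top.
#'
#' @param config a [sim_config()]; uses `seed`, `n_trend_templates`, `noise_sd`.
#' @param n_genes number of genes to draw.
#' @param n_cells number of cells, with pseudotime uniform on [0,1].
#' @return list with `expr` (gene x cell matrix), `pseudotime` (length
#'   `n_cells`, in [0,1]) and `template_of_gene` (integer vector).
#' @export
simulate_trend_profiles <- function(config = sim_config(), n_genes = 200,
                                    n_cells = 2000) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    s <- stats::runif(n_cells)
    tpl <- trend_templates(s, config$n_trend_templates)
    template_of_gene <- rep_len(seq_len(config$n_trend_templates), n_genes)
    expr <- tpl[, template_of_gene, drop = FALSE]
    expr <- t(expr) + matrix(stats::rnorm(n_genes * n_cells, 0, config$noise_sd),
                             nrow = n_genes)
    rownames(expr) <- sprintf("tgene%04d", seq_len(n_genes))
    colnames(expr) <- sprintf("tcell%04d", seq_len(n_cells))
    list(expr = expr, pseudotime = s,
         template_of_gene = stats::setNames(template_of_gene, rownames(expr)))
  })
}
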