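---
title: "Methods: paired scRNA/scATAC analysis of myogenic differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired scRNA/scATAC analysis of myogenic differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and design

`myomultiome` implements the computational core of an integrative
single-cell RNA + ATAC analysis of embryonic skeletal-muscle development:
quality control for both modalities, genomic element stratification of open
chromatin, differential expression and accessibility, gene activity
scoring, motif enrichment, cis-regulatory peak–gene linking, cross-modality
correlation of cell-type assignments, and pseudotime trend clustering. The
biological system it targets is the myogenic lineage of the somite —
Pax3⁺ progenitors differentiating through myogenic progenitors and
myoblasts into myocytes along a single main trajectory.

Upstream steps that belong to vendor or third-party pipelines — read
alignment, peak calling, graph-based clustering, embedding, trajectory
*inference*, anchor-based label transfer, regulon inference — are
deliberately inputs, not computations. The package consumes count
matrices, a fragments file, an annotation, a peak list, a motif occurrence
table and per-cell metadata (labels, pseudotime), and everything downstream
of those inputs is implemented and tested here.

# The synthetic multiome generator

Because the package's statistics operate on data whose generating process
is well understood, validation is built around a paired-multiome simulator
with planted ground truth (`sim_config()`, `simulate_annotation()`,
`simulate_multiome()`).

**Trajectory.** Cells belong to one of four ordered types
(`Pax3P → MyoP → Myob → Myoc`) arranged along a linear trajectory;
pseudotime is uniform within contiguous per-type windows of $[0,1]$. A
linear, single-branch trajectory is the appropriate model here because the
lineage of interest is the single main myogenic branch (the off-branch
cardiomyocyte population is an exclusion step upstream of these analyses).

**RNA counts.** Counts are negative binomial with size (dispersion)
parameter 2 and a baseline mean of 0.5 per gene per cell. Each type owns a
disjoint 10% of genes as markers; a marker's mean is lifted by a factor up
to 8 (a typical strong-marker effect), modulated over pseudotime by the
gene's trend template so that the lift peaks inside the focal type's
pseudotime window. Mitochondrial genes on a separate contig contribute 2%
of counts in expectation.

**Trend templates.** The default five templates are piecewise-smooth
functions of scaled pseudotime with the shapes seen in staged
differentiation data: early-high decreasing, mid-early peak, broad mid,
late rise-and-hold, and terminal-only. They are exposed directly
(`trend_templates()`) and through `simulate_trend_profiles()`, which
generates continuous template + Gaussian noise profiles (`noise_sd`,
default 0.1) used to validate trend-curve estimation and clustering
without count noise on top.

**ATAC counts.** Peak detection is Bernoulli with background probability
0.05 and focal-type probability 0.60 for planted type-specific peaks (5% of
peaks per type, disjoint across types); detected entries get $1 +$ Poisson
counts. Specific peaks are preferentially placed at the focal type's marker
genes (gene body + 2 kb upstream, excluding the TSS) — as marker loci are
in real data — and otherwise within ±100 kb of a marker TSS, which makes
the planted peaks simultaneously (a) recoverable by differential
accessibility, (b) valid material for cis-link recovery and (c) the source
of type-specific gene activity for cross-modality validation.

**Fragments.** Fragment lengths follow a sub-nucleosomal (normal around
75 bp), mono-nucleosomal (around 200 bp) and di-nucleosomal (around 380 bp)
mixture with weights 0.60/0.35/0.05; 65% of fragments fall inside peaks,
25% are centred near TSSs (s.d. 120 bp), the rest are uniform. The
mitochondrial fragment rate defaults to 0.5% — a deliberate, realistic
choice distinct from the RNA mitochondrial fraction, since ATAC libraries
typically carry far less mitochondrial signal relative to the 2% filter
than RNA libraries do relative to the 10% filter. Doublets (2% of
barcodes) are sums of two random cells in both modalities.

**What the generator does not emulate.** Batch effects, ambient RNA,
read-level sequence, GC-dependent accessibility bias, and correlated
(co-accessible) peak structure. Tests passing on this generator therefore
validate the statistical machinery and its contracts, not robustness to
those real-data artefacts.

**Problem sizes.** The default configuration — 4 types × 500 cells, 200
genes, 1,000 peaks, one 20-Mb chromosome — is the condition under which
planted-recovery results are reported. QC demonstrations use a deeper
configuration (1,000 genes, ~3,000 fragments per cell) because the
absolute thresholds (200 genes detected, 2,000 fragments) presuppose
library depths of that order.

# Quality control

RNA per-cell metrics are direct sums: genes detected (count > 0), UMI
total, mitochondrial fraction, and a doublet flag at > 40,000 transcripts.
Cells are removed below 200 detected genes, above 30,000 UMIs, above 10%
mitochondrial counts, or when flagged; genes detected in fewer than 3
surviving cells are then removed (exactly 3 survives). The 30,000-UMI
removal bound and the 40,000-transcript doublet flag overlap; the stricter
bound governs removal and the flag is kept for reporting. All-zero cells
get `mito_fraction = 0` rather than 0/0 — they are removed by the
gene-count rule regardless.

ATAC barcodes are kept with 2,000–30,000 fragments (inclusive),
mitochondrial ratio strictly below 2%, TSS enrichment strictly inside
(2, 40), nucleosome signal strictly below 5 and FRiP strictly above 50%.
`nucleosome_signal` is the count of mono-nucleosomal fragments
(147–294 bp) over sub-nucleosomal fragments (< 147 bp), denominator
floored at 1. FRiP counts fragments overlapping any peak by ≥ 1 bp
(fragments, not reads, are what a fragments file carries).

**TSS enrichment.** Both fragment ends are insertion events. Insertions
within ±1 kb of any TSS are binned by signed, strand-aware distance; the
score is

$$\mathrm{TSSe} = \frac{\bar s + c}{\bar b + c},$$

where $\bar s$ is the mean per-base insertion count over $|d| \le 500$,
$\bar b$ the mean over the outermost 100-bp flanks ($900 < |d| \le 1000$),
and $c$ half the cell's mean per-base count over the whole window. Adding
the pseudocount to *both* numerator and denominator stabilises sparse
cells while keeping the defining calibration property — a cell with
uniform insertions scores ≈ 1 — which a denominator-only pseudocount would
break (it biases every score toward 2/3). The statistic is monotone in
genuine TSS enrichment either way; this form is the one whose null value
is interpretable.

# Genomic element stratification

Gene annotation is held 0-based half-open internally (GTF converts on
read/write). Promoters are the 2 kb upstream of the TSS, strand-aware,
clipped at zero. Peaks detected in **more than** 10% of the cells of
interest are classified by the priority order

> exon > promoter > 5′-UTR > 3′-UTR > intron > distal,

with overlap meaning ≥ 1 shared base. The exon class refers to the
CDS-bearing exon body: where UTR annotation exists, UTR portions of
terminal exons are carved out and compete as their own classes; a gene
without UTR annotation contributes whole exons. This makes the six classes
well-defined under the stated priority (otherwise every 5′-UTR peak would
be an exon peak and the UTR classes could never occur). A peak overlapping
a gene body but none of the higher classes is intronic; anything else is
distal. The classifier is validated against a quadratic brute-force
interval scan on random toy genomes.

# Differential testing

**Normalization and logFC.** Expression is `ln(1 + 10^4 · c / colsum)`.
Log fold change between groups is computed on back-transformed normalized
means: `ln((m_a + 1)/(m_b + 1))`, natural log — the convention from which
the 0.25 threshold originates.

**Pre-filter.** For both modalities a feature is tested only if detected
in at least 10% of one group and |logFC| ≥ 0.25. For binarized
accessibility the logFC uses detection-fraction pseudomeans
`ln((pct_a + ε)/(pct_b + ε))`, ε = 10⁻³, since a count-scale formula is
not meaningful for binary data.

**Wilcoxon rank-sum (RNA).** Mid-ranks for ties. With ≤ 20 cells combined,
the exact two-sided p comes from full enumeration of group-a rank
assignments, `p = min(1, 2·min(P(W ≤ w), P(W ≥ w)))`; otherwise a normal
approximation with tie correction and 0.5 continuity correction. The two
branches agree within 0.02 at 10 + 10 cells.

**Fisher exact (ATAC).** Accessibility binarized as count > 0; per peak a
2×2 table at fixed margins; two-sided p by the minimum-likelihood rule —
the sum of hypergeometric point probabilities not exceeding the observed
one (with the customary 1 + 10⁻⁷ relative slack against floating-point
ties). This matches full enumeration to < 10⁻¹² for every table with
margins ≤ 30.

**Logistic regression (ATAC).** Likelihood-ratio test of
`logit(accessible) ~ group + covariate` against the covariate-only model,
χ²(1), with the per-cell total fragments-in-peaks as the covariate
(standardized internally). Fitting is IRLS, ≤ 100 iterations, tolerance
10⁻⁸; on (near-)separation the fit repeats with a ridge penalty of 10⁻⁶
and the record is flagged rather than dropped.

**Multiple testing.** BH step-up by default over the tested features;
Bonferroni available via `method = "bonferroni"` (both corrections are in
circulation for this kind of analysis; BH is the default because it is the
one attached to the stated 0.05 threshold for DE/DAP calls). Significance
is adjusted p < 0.05.

**Cell-type-specific peaks.** All-pairs dominance: a peak is specific to
type *t* iff every pairwise Fisher test against another type is
significant with the higher detection fraction in *t*. This is the
strictest consistent reading of "pairwise tests between every cluster" and
makes the per-type sets disjoint by construction. Shared/unique accounting
(`shared_unique_peaks()`) counts exclusive intersections of per-type
accessible sets (detected in > 10% of a type's cells) for every non-empty
type subset.

# Gene activity and standardization

`gene_activity()` sums, per cell, the fragment counts of all peaks
overlapping the gene window: gene body + 2 kb upstream (strand-aware;
default) or gene body ± 2 kb (the variant used for marker-gene dot plots).
Both window conventions appear in practice, so both are shipped; upstream
only is the default because it matches the gene-activity definition used
for cross-modality work. Peaks in several windows count in each — per-gene
summation as defined, so totals may double-count. Genes on X/Y/M contigs
can be dropped by flag.

`standardized_accessibility()` maps a per-cluster mean vector to [0,1] by
subtracting the minimum and dividing by the maximum *of the min-subtracted
values*. The divisor choice (max after subtraction, not the raw max)
guarantees the 0–1 range that the display convention evidently intends;
constant vectors return zeros with a warning.

# Motif enrichment

For specific set size $n$, motif count $x$ and background frequency
$p_0$:

$$z = \frac{x - n p_0 - 0.5\,s}{\sqrt{n p_0 (1 - p_0)}},\qquad
s = \operatorname{sign}(x - n p_0)\ (s = +1\ \text{at}\ x = n p_0),$$

a continuity-corrected binomial deviation. The "modified z-score" this
stands in for is a vendor algorithm whose exact constants are
version-dependent and unpublished; the binomial form preserves the
statistic's monotone ordering — which is all that downstream rankings
consume — and is fully testable: its tail matches a Monte-Carlo resampling
oracle within a factor of ~2 for |z| ≤ 3. Motifs with $p_0 \in \{0, 1\}$
are skipped (NA) with a warning. Optional GC matching resamples the
background to the specific set's GC-decile composition before computing
$p_0$; it requires per-peak GC values, which are an input (the package does
not scan sequence). PWM scanning is likewise out of scope: occurrences
arrive as a table.

# Cis-regulatory linking

Two link types, disjoint by construction:

* **direct** — the peak interval contains the TSS coordinate (half-open:
  `start ≤ TSS < end`);
* **co-enrichment** — gene and peak are specific to the same cell type,
  the peak overlaps the closed ±100 kb window around the TSS (any overlap,
  the inclusive reading, since a midpoint rule is not implied by "within
  ±100 kb"), and the peak does **not** contain the TSS.

Links are many-to-many; each carries a signed, strand-aware TSS-to-midpoint
distance. Every emitted link is re-checkable by independent rule
evaluation, and the planted links of the generator are recovered whenever
their gene and peak survive differential testing.

# Cross-modality correlation

Variable genes are chosen by binned standardized dispersion: genes are
binned (20 equal-frequency bins, shrunk when few genes are available) by
mean normalized expression; within each bin the variance/mean dispersion
is z-scored; the top *n* (default 2,000, the convention of the ecosystem
this analysis style comes from) are kept. The confusion matrix is the
Pearson correlation, over those genes, of per-type mean gene activity
(ATAC) against per-type mean expression (RNA); each ATAC type's predicted
RNA type is its row argmax. On the matched generator at default effect
sizes the argmax recovers all four types and the diagonal dominates the
off-diagonal by > 0.2.

# Pseudotime trend analytics

Pseudotime (an input — ordering is upstream) is rescaled linearly to
[0,100]. The unit of a cell is `floor(s)` with s = 100 assigned to unit
100, giving 101 integer units — the natural reading of "per pseudotime
unit" on a [0,100] axis. A gene's curve is the per-unit mean of normalized
expression; empty units are linearly interpolated (nearest value at the
ends) and a centred moving average (window 5, on by default) smooths the
curve.

Curves are z-scored across units and clustered by Ward linkage (ward.D2)
on Euclidean distance, cut at k = 5. The linkage is a documented choice —
the clustering heatmap tools this mirrors do not pin one down — and is
validated by template recovery (ARI ≥ 0.9 against the five planted shapes
at noise 0.1) rather than by matching any package bit-for-bit. Clusters
are renumbered by ascending argmax of their mean curve, so cluster 1 peaks
earliest.

Phase scoring is a marker-score stand-in for package-internal cell-cycle
callers: per-gene z-scores across cells averaged over an S set and a G2M
set; G1 iff both ≤ 0, otherwise the larger score (ties to S). Only the
downstream proportions interface (`phase_proportions()`, rows summing
to 1) is contract-bound; the generator plants no cycle program, so the
workflow demonstrates the mechanics with illustrative gene sets.

# Numerical and degenerate-input conventions

* Zero-total cells are an error in `normalize_rna()` (filter first).
* A feature constant across both groups gets p = 1.
* Fisher p is clamped to ≤ 1 after summation (guards 10⁻¹⁶ overshoot).
* Empty ATAC barcodes get all-zero QC metrics, not errors.
* Constant pseudotime, empty cell subsets, unknown contigs, unknown gene
  or mitochondrial feature ids are explicit errors.
* All randomness in the generator is governed by `sim_config()$seed`; the
  generator saves and restores the caller's RNG state.

# Known limitations

* The Fisher/logistic DAP machinery treats cells as exchangeable within
  groups; no per-sample (pseudobulk) aggregation or batch covariates.
* Gene activity uses unweighted sums — no distance decay, no
  co-accessibility model.
* The motif statistic is marginal per motif; no GC-bias correction beyond
  optional decile matching, no per-cell deviation scores.
* Trend clustering assumes curves on a shared [0,100] support; branching
  trajectories must be split upstream.
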