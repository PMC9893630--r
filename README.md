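# myomultiome

Joint analysis of paired single-cell RNA-seq and single-cell ATAC-seq data
along a myogenic differentiation trajectory (Pax3⁺ progenitor → myogenic
progenitor → myoblast → myocyte), for researchers studying the
transcriptional and chromatin-accessibility programs of embryonic skeletal
muscle — or any staged differentiation system with paired multiome data.

The package implements, as tested reusable functions:

* **Quality control** — RNA: genes detected, UMIs, mitochondrial fraction,
  doublet flag (> 40,000 transcripts); filters at < 200 genes, > 30,000
  UMIs, > 10% mito. ATAC: fragment count, mitochondrial ratio, TSS
  enrichment, nucleosome signal, FRiP; filters at 2,000–30,000 fragments,
  < 2% mito, TSS enrichment in (2, 40), nucleosome signal < 5, FRiP > 50%.
* **Genomic element stratification** of open chromatin by the priority
  order exon > promoter > 5′-UTR > 3′-UTR > intron > distal (2-kb
  promoters; peaks detected in > 10% of cells).
* **Differential testing** — Wilcoxon rank-sum DE (exact enumeration at
  small n, tie-corrected normal approximation otherwise); Fisher exact and
  logistic-regression (fragments-in-peaks covariate, LRT) differential
  accessibility; both with the 10%-detection / 0.25-logFC pre-filter and
  BH (or Bonferroni) correction; all-pairs-dominance cell-type-specific
  peak calling; shared/unique peak accounting.
* **Gene activity scores** (gene body + 2 kb upstream, or ± 2 kb flanks)
  and [0,1]-standardized per-cluster accessibility.
* **Motif enrichment** by a continuity-corrected binomial z-score
  `z = (x − n·p₀ − 0.5·s)/√(n·p₀(1−p₀))` of motif occurrences in
  cell-type-specific peaks against a (optionally GC-matched) background.
* **Cis-regulatory linking** — direct (peak contains the TSS) and
  co-enrichment (same-type gene and peak within ±100 kb of the TSS, TSS
  not inside the peak).
* **Cross-modality validation** — per-type Pearson correlation of average
  gene activity vs average expression over variable genes, with argmax
  type prediction.
* **Pseudotime trend analytics** — [0,100] rescaling, per-unit mean
  curves, five-cluster Ward/Euclidean trend grouping ordered early → late,
  marker-score phase calls and per-state phase proportions.
* **A synthetic paired-multiome generator** with planted ground truth
  (marker genes with pseudotime trend templates, type-specific peaks, cis
  links, motifs, doublets, bimodal fragment sizes, TSS-enriched
  insertions) driving end-to-end recovery tests.

See `vignettes/myomultiome-methods.Rmd` for the statistical details and
design decisions.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Step 1
simulates a paired multiome (800 cells + 16 doublets, 1,000 genes, 1,000
peaks) and writes it in standard formats (MTX, BED, GTF, fragments TSV);
the later steps read those files back and analyse them.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc.R
Rscript analysis/04_differential.R
```

Step 2 prints the QC outcome — the simulated cells are healthy apart from
a tail of shallow ATAC barcodes:

```
RNA:  816 cells -> 816 kept; genes: 1005 -> 1005
ATAC: 816 cells -> 800 kept
 cells_bad_fragments ... 16
median TSS enrichment: 3.03  median nucleosome signal: 0.58  median FRiP: 0.683
```

Step 4 runs one-vs-rest DE per type and the pairwise-Fisher specific-peak
calling, then scores it against the generator's planted truth:

```
upregulated DE genes per type: 119 116 108 134
cell-type-specific peaks (Fisher, all-pairs dominance): 51 50 50 50
planted-peak recovery: 100.0%; misassignment: 0.5%
logistic vs Fisher on Pax3P vs MyoP: 110 peaks tested, 100.0% concordant calls
```

i.e. all 200 planted type-specific peaks are recovered, with a single
background peak miscalled, and the logistic-regression test agrees with
Fisher on every tested peak of the first pair. Step 5 links peaks to genes
(55 direct TSS links, 316 co-enrichment links, median distance 4.4 kb) and
ranks the planted motif first for all four types (z between 9 and 13);
step 6 clusters 553 DE-gene trend curves into five groups peaking at
pseudotime units 0, 34, 53, 83 and 100 and cross-validates the modalities
— every ATAC type's activity profile correlates best with its own RNA
type.

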