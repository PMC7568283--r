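---
title: "Methods: case/control snRNA-seq analysis with disease-associated subpopulation detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case/control snRNA-seq analysis with disease-associated subpopulation detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`nucleoshift` implements a complete case/control single-nucleus RNA-seq
analysis for cohort designs of the kind used in postmortem brain studies
of Alzheimer's disease (AD) versus normal controls (NC): per-nucleus
quality control, normalization, clustering and marker-based cell-type
annotation, per-cell-type differential expression, and — the analytical
core — a DEG-enrichment z-score procedure that classifies
disease-associated cell subpopulations within each type and quantifies
how their within-type proportions shift between conditions. A
negative-binomial cohort simulator with full ground truth backs every
stage with recovery benchmarks.

# Quality control

A nucleus is removed when any of three conditions holds: at most 200
detected genes, at least 20,000 total UMIs, or a mitochondrial UMI
fraction of at least 20%. The boundary values are removal-inclusive
(`apply_qc_filters()` keeps only cells satisfying all three strict
inequalities), reading the removal rule verbatim. Mitochondrial genes
are identified by the `MT-` symbol prefix by default; an explicit gene
list or predicate can be supplied, since published analyses rarely state
their exact mitochondrial set. The mitochondrial fraction is computed
over UMIs, the standard practice, and filtering is idempotent by
construction. Upstream cell calling (distinguishing barcodes containing
nuclei from ambient droplets) is assumed already done; the pipeline
takes called count matrices as input.

Per-sample mean genes/nucleus and UMIs/nucleus are additionally tested
for dependence on postmortem delay (`pmd_independence()`: Pearson
correlation, two-sided t-test on n − 2 df) — a non-significant result
supports treating sample quality as unconfounded with the postmortem
interval.

# Normalization, variable genes, embedding, clustering

Counts are library-size normalized and log-transformed
(`ln(1 + 10^4 x / total)`). Variable genes are ranked by
variance-stabilized standardized variance: a loess trend (span 0.3,
degree 2) of log10 variance on log10 mean over raw counts, each gene
standardized by its fitted standard deviation with values clipped at
√n_cells, genes ranked by the variance of the clipped values; the top
1000 are kept. For very small or degenerate inputs (fewer than ten
usable genes, collapsed mean range, non-finite loess fits) the trend
falls back to a linear, then a flat, fit. Ties in the ranking are broken
lexicographically by gene name so the selection is deterministic.

Selected genes are scaled to zero mean and unit variance (values clipped
at ±10) and cells embedded with PCA (50 components computed, the first
20 used). The sign of each component is fixed so its largest-magnitude
gene loading is positive, making embeddings reproducible run-to-run.
Cells are then clustered on a shared-nearest-neighbor graph (Euclidean
k = 20 including self, edges weighted by neighbor-set Jaccard overlap,
pruned below 1/15) by Louvain modularity optimization at resolution 1,
labels renumbered by decreasing size. The reference toolchain for this
kind of analysis integrates samples with anchor-based CCA before
clustering; reproducing those internals is out of scope here, so scaling
is computed on the pooled cohort. The simulator plants no batch effects,
and on real data with strong batch structure a dedicated integration
step would be needed upstream — recovery results on synthetic cohorts do
not speak to that failure mode. Because modularity optimization at
resolution 1 legitimately oversplits large homogeneous populations,
recovery is assessed on annotated cell types, not on raw cluster-label
equality, mirroring how such pipelines are used in practice (multiple
clusters per type are collapsed by annotation).

Cluster annotation scores each cluster per type as the mean across the
type's reference markers (astrocyte AQP4, endothelial CLDN5, excitatory
neuron CAMK2A, inhibitory neuron GAD1, microglia C3, oligodendrocyte
MBP) of the marker's cluster-mean expression z-scored across clusters;
the argmax wins, and a cluster whose best score does not exceed the
runner-up is `unassigned`.

# Differential expression

Within each annotated type, case and control cells are compared gene by
gene with the two-sided Wilcoxon rank-sum test on normalized expression
— cells, not subjects, are the test units, as is standard for this
design (a consequence is that p-values do not account for
between-subject correlation; the proportion-shift analysis, by
contrast, uses subjects as units). The implementation uses the exact
rank-sum null for small tie-free inputs and otherwise the normal
approximation with tie correction and continuity correction. The fold
change is computed on de-logged normalized means,
`log2((mean(exp(case) − 1) + ε) / (mean(exp(control) − 1) + ε))` with
ε = 10⁻⁹, positive when expression is higher in cases. P-values are
adjusted within each type's tested gene set — Bonferroni by default
(the convention of the toolchain this design follows; published
analyses usually report only "adjusted P"), Benjamini–Hochberg
selectable. A gene is a DEG when adjusted P < 0.1 and |log2FC| ≥ 0.1.
Genes without expression in a type are untestable and omitted. Cluster
markers use the same machinery one-vs-rest with a |log2FC| ≥ 0.25
pre-filter.

# Disease-associated subpopulations

Each analysed type (glial and endothelial compartments by default;
neurons are excluded, overridable) is re-clustered with the same recipe
at a per-type resolution (astrocytes 0.2, endothelial 0.2, microglia
0.3, oligodendrocytes 0.2). For the enrichment score, every
condition-DEG of the type has its normalized expression z-scored across
*all* cells of the type; a subpopulation's score for a direction (up- or
down-regulated DEG set, scored separately) is the mean of those z-values
over its cells and genes. Two consequences drive the design choice of
z-scoring per cell rather than on subpopulation means:

* the cell-count-weighted mean of any score over a type's
  subpopulations is exactly 0 (a testable identity), and
* scores are comparable across subpopulations of different sizes.

A subpopulation scoring strictly above 0.5 in a direction is classified
`up_regulated`/`down_regulated`; if both directions exceed the
threshold the larger wins and an exact tie is `ambiguous`. The
centering also bounds attainable scores: a subpopulation holding share
s of the type can reach at most (1 − s) times the per-gene z-shift of
its program, so a compartment-dominating subpopulation can never score
high — the statistic is intrinsically geared to minority
subpopulations. Classification is monotone in the threshold. Zero
variance genes contribute z = 0, and an empty DEG set for a direction
yields a null score rather than 0.

Signatures of disease-associated subpopulations come from pooled
up-regulated versus pooled down-regulated cells through the same DE
machinery and thresholds. Proportion shifts use the subject as the
statistical unit: per-sample within-type subpopulation proportions,
summarised per condition as mean ± SEM, with the shift reported both in
percentage points (`delta_pp`) and relative to the control mean
(`delta_relative`) — "X% larger" is ambiguous between the two, so both
are always emitted.

# Cross-study concordance

Given an external DE table (gene, signed effect, adjusted p — e.g. a
limma fit of a microarray cohort), genes are matched by normalized
symbol, external duplicates collapsed to the median effect, and
"replicable" DEGs counted at external adjusted P < 0.05 (strict).
Direction concordance is the percentage of replicable genes with
agreeing effect signs, excluding exact-zero effects, reported pooled
and per cell type (published figures in this design typically pool; the
per-type table disambiguates).

# The cohort simulator

`generate_cohort()` draws UMI counts gene-by-cell from a negative
binomial with mean
`libsize_factor × baseline_mean × 2^(applicable effects)` and a single
shared dispersion (size = 1/dispersion, default dispersion 0.5) — one
knob, the standard UMI noise model. Baseline means are lognormal with
median 0.2 counts/cell (sdlog 1.0), mimicking sparse snRNA-seq;
library-size factors are lognormal with mean 1 (sdlog 0.35). Effects
are multiplicative: type markers (default 25 genes at log2FC 3 per
type), optional condition-independent subpopulation programs (which
make planted subpopulations discoverable by re-clustering — shares
alone carry no expression signal), and planted condition DEGs applied
to case cells of a type (or of one subpopulation). Thirteen `MT-` genes
receive means calibrated to an expected 5% mitochondrial share.

The default cohort design mirrors the motivating study: 12 case and 9
control subjects, six cortical types at proportions 11.9 / 2.3 / 45.2 /
14.1 / 4.7 / 21.8% (astrocytes, endothelial, excitatory, inhibitory,
microglia, oligodendrocytes), Braak-consistent metadata (cases ≥ 4,
controls ≤ 2), case/control age means 74.6/85.4, a 2:1 male:female
ratio. Scale defaults (1000 cells/sample, 2000 genes) are desk-scale
choices — depth per cell, not cohort structure, is what they reduce —
chosen so a default cohort generates in seconds. Note that with the
median gene mean of 0.2 counts/cell, a realistic 200-detected-gene QC
floor requires roughly ≥ 2000 genes; tiny gene panels would flunk QC
wholesale.

Debris nuclei (default 5% per sample) are planted violators: half have
their library collapsed to ~60 expected UMIs (far below the
200-detected-genes floor), half receive an expected mitochondrial share
of 0.5. The 0.5 target (rather than just above 0.2) is deliberate: with
13 mitochondrial genes and dispersion 0.5, the realized mito share has
a standard deviation of several percentage points, and planted
violators must violate with near-certainty for the exact-filtering
benchmark to be meaningful. `make_qc_fixture()` goes further and
constructs violators deterministically, including cells sitting exactly
on each boundary. `null_cohort()` strips every condition effect —
no planted DEGs, equal subpopulation shares — for type-I-error
calibration. All output is bit-reproducible given the config seed.

What the simulator does **not** emulate: gene–gene correlation beyond
the planted programs, ambient RNA, doublets, batch effects, or
subject-level expression random effects. Passing recovery benchmarks
therefore demonstrates correctness of the implemented procedures under
the stated model, not robustness to those real-data phenomena.

# Benchmark problem sizes and numerical choices

The test suite and `scripts/acceptance.R` run, per stage: exact
rank-sum p-values against full enumeration (all tie-free inputs up to
n = 12); adjustment against independently coded oracles (1000 random
vectors); exact QC filtering on the deterministic fixture (500 cells,
37 planted violators); type-I calibration on a 4+4 × 500-cell,
2000-gene null cohort (per-type fraction of raw p < 0.05 inside the
binomial 99% band); recovery of 50 planted |log2FC| = 1 DEGs in a
6+6 × 600-cell cohort (sensitivity ≥ 0.8 at Bonferroni-adjusted
P < 0.1, observed ~0.86–0.90, empirical FDR ≤ 0.15, observed 0);
annotation recovery on a 4+4 × 500-cell cohort (adjusted Rand index of
annotated types vs truth ≥ 0.8, observed ~1.0); enrichment-score
recovery over 10 seeds of a 4 × 400-cell design where one
20%-share subpopulation carries a 30-gene 4× program on well-expressed
genes (base mean 2 counts/cell) — the bound above explains why a
large-share subpopulation with a weak program is not detectable at the
0.5 threshold, so the benchmark plants the regime the statistic is
designed for; matched nulls must stay below 0.25 in magnitude; the
centering identity to 10⁻⁹; and a planted 20-percentage-point
proportion shift recovered within ±5 pp on a 6+6 × 1000-cell cohort
(at ~220 cells of the type per sample the sampling SE of the estimate
is ~2 pp, so the tolerance tests method bias rather than counting
noise).

Numerical conventions throughout: lexicographic tie-breaks for gene and
cluster orderings; cluster labels renumbered by decreasing size; PCA
signs fixed by the largest loading; ε = 10⁻⁹ pseudocount in fold
changes; degenerate inputs (all-identical test values, zero-variance
genes, empty compartments, samples without cells of a type) handled
explicitly with flags or warnings rather than NaNs.

# Known limitations

Cell-level DE p-values ignore subject-level correlation (a pseudobulk
mode would be the remedy; the cell-level test is what this design
prescribes). No batch integration. The 0.5 enrichment threshold is a
convention, not a calibrated error rate — on null cohorts scores
concentrate well below 0.25 at realistic compartment sizes, but the
threshold's operating characteristics depend on DEG-set size and
compartment depth. Subpopulation reports carry scores and
classifications only; biological naming is left to the analyst.
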