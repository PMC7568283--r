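# nucleoshift

Case/control single-nucleus RNA-seq analysis with detection of
disease-associated cell subpopulations and their proportion shifts.

Postmortem-brain snRNA-seq studies of Alzheimer's disease (AD) versus
normal controls (NC) ask two questions per cell type: *which genes
change* (per-type differential expression) and *which cells carry the
change* (are the DEGs driven by a transcriptomically distinct
subpopulation whose abundance shifts with disease?). `nucleoshift`
implements the full pipeline for both, plus a ground-truthed synthetic
cohort generator to benchmark every stage. It is aimed at analysts who
have per-sample 10x-convention count matrices (or want simulated ones)
and a sample sheet with condition labels.

## The statistics at the core

For cell type *t* with case/control cells, each gene *g* is tested with
the two-sided Wilcoxon rank-sum test on log-normalized expression
(`ln(1 + 10⁴·x/total)`), with fold change

    log2FC(g) = log2( (mean(exp(case)−1) + ε) / (mean(exp(control)−1) + ε) ),  ε = 1e−9

and a DEG called at adjusted *P* < 0.1 (Bonferroni within the type's
tested genes, BH selectable) and |log2FC| ≥ 0.1.

Each type is then re-clustered into subpopulations (shared-nearest-
neighbor graph, Louvain modularity at per-type resolutions
0.2/0.2/0.3/0.2 for astrocytes/endothelial/microglia/oligodendrocytes).
The **enrichment score** of subpopulation *s* for a DEG direction
*D* ∈ {up, down} is

    score_D(s) = mean over g ∈ D, c ∈ s of z_g(c)

where `z_g` is gene *g*'s expression z-scored across **all** cells of
the type. A subpopulation with a score > 0.5 is classified as
disease-associated (up- or down-regulated); its within-type proportion
per sample yields condition means ± SEM and the shift in percentage
points and relative terms, with the *subject* as the unit. An external
DE table (e.g. a microarray cohort) can be matched by gene symbol to
count replicable DEGs (external adjusted *P* < 0.05) and the
direction-concordance percentage.

On-disk formats: Matrix Market coordinate integer with 1-based indices
and genes as rows (the 10x convention) plus `features.tsv`/
`barcodes.tsv` (gzip read transparently; writes are plain text), and
headered CSV for all tables. Barcodes are namespaced
`"<sample_id>:<barcode>"` when samples are pooled.

## Worked example

Simulate an 8-subject cohort in which oligodendrocytes carry 30 planted
type-wide DEGs (log2FC 1.5, up in AD) and a three-subpopulation
structure whose first subpopulation shrinks from 50% to 30% of the type
in AD, then run the whole pipeline:

```r
library(nucleoshift)

cfg <- cohort_config(
  n_samples_case = 4, n_samples_control = 4, cells_per_sample = 500,
  n_genes = 2000,
  subpops = tibble::tibble(
    cell_type = "oligodendrocyte", name = c("o1", "o2", "o3"),
    baseline_share_within_type = c(0.5, 0.3, 0.2),
    case_share_within_type    = c(0.3, 0.5, 0.2),
    marker_genes = 25L, marker_log2fc = 3, marker_base_mean = 1),
  planted_degs = tibble::tibble(
    cell_type = "oligodendrocyte", subpop = "all",
    gene_count = 30L, log2fc = 1.5),
  seed = 42)

cohort <- generate_cohort(cfg)
result <- run_all(cohort, config = pipeline_config(seed = 42))
#> qc: kept 3793 of 4000 nuclei across 8 samples
#> cluster: 9 clusters -> 6 cell types
#> de: 36 significant DEGs across 6 cell types

glance(result$de)
#> # A tibble: 6 x 5
#>   cell_type         n_tested n_significant  n_up n_down
#> 1 astrocyte             2000             0     0      0
#> 2 endothelial           1972             0     0      0
#> 3 excitatory_neuron     2000             0     0      0
#> 4 inhibitory_neuron     2000             0     0      0
#> 5 microglia             1996             0     0      0
#> 6 oligodendrocyte       2000            36    25     11

rep <- tidy(result$subpop)
rep[rep$cell_type == "oligodendrocyte",
    c("subpop", "n_cells", "up_score", "down_score", "classification",
      "mean_case", "mean_control", "delta_pp")]
#> # A tibble: 3 x 8
#>   subpop n_cells  up_score down_score classification mean_case mean_control
#> 1 s1         363  0.0559       -0.518 unaffected         0.506        0.357
#> 2 s2         320 -0.0638        0.831 down_regulated     0.298        0.468
#> 3 s3         155  0.000856     -0.504 unaffected         0.196        0.175
```

Reading the output: DE fires only in oligodendrocytes — the 25
recovered planted up-DEGs plus 11 down-DEGs. Those down-DEGs are real
signal, not noise: the shrinking subpopulation `o1` over-expresses its
own 25-gene program, so as its share drops in AD those genes fall at
the whole-type level. The enrichment procedure then attributes them
back to their source — recovered subpopulation `s2` (which is `o1`:
proportion 0.47 → 0.30, `delta_pp` ≈ −17 against the planted −20)
scores 0.83 on the down-DEG set and is classified `down_regulated`,
while both stable subpopulations stay below the 0.5 threshold. This is
precisely the inference the method exists for: locating which
subpopulation's gain or loss produces a cell type's disease signature.

`autoplot(result$de)` draws per-type volcano plots,
`autoplot(result$subpop)` the subpopulation proportions by condition,
and `plot_qc(tidy(result))` the QC metric distributions.
`run_all(..., out_dir = "out/")` writes `qc_summary.csv`,
`cell_table.csv`, `de_table.csv`, `subpop_report.csv` and a
`manifest.json` with the seed and config hash. A thin command-line
wrapper (`inst/scripts/nucleoshift.R`, subcommands `simulate`,
`run-all`, `concord`) drives the same functions file-to-file.

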