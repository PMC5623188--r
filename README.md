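# gangliaDE

Comparative transcriptomics of FACS-enriched sensory neuron populations:
dorsal root ganglion (DRG, condition **A**) versus trigeminal ganglion (TG,
condition **B**) neurons profiled by bulk RNA-seq with unbalanced
replication (typically 6 vs 4). Whole-ganglion comparisons are confounded by
non-neuronal cells — satellite glia, myelin, macrophages — so genes that
differ between ganglia may not differ between *neurons*. This package
implements the neuron-enriched analysis that addresses that: a permissive
expression call, a negative-binomial differential expression test, and two
screens (expression cut-off, neuronal-origin reference set) applied before
any gene is declared upregulated or *exclusive* to one ganglion. It is aimed
at analysts working with sorted-population RNA-seq who want every stage of
that pipeline as a tested, scriptable R function.

## What it computes

* **FPKM and presence calls** — `fpkm = counts · 10⁹ / (total · length_bp)`;
  a gene is present in a condition when ≥ 2 replicates reach FPKM ≥ 1, and
  detected when present in either condition.
* **NB Wald differential expression** (`estimate_size_factors`,
  `estimate_dispersion`, `nb_wald_test`, `adjust_bh`) — median-of-ratios
  normalization; method-of-moments dispersions shrunk toward a
  bias-corrected `α(μ) = a₁/μ + a₀` trend with an adaptive weight calibrated
  by a parametric resample; Wald statistic `log2(μ̂_B/μ̂_A) / SE` with
  delta-method SE under `Var = μ + αμ²`; two-sided normal p-values;
  Benjamini–Hochberg FDR.
* **Classification** (`classify_genes`) — decision order: not significant →
  common; significant but failing the expression cut-off → not_expressed;
  absent from the pure-neuron reference → non_neuronal; present in one
  condition only → exclusive; otherwise up_a / up_b by fold-change sign.
* **Concordance** (`rank_correlation`, `presence_agreement_topk`,
  `joint_presence_summary`, `trend_concordance`,
  `standardized_heatmap_matrix`) — cross-dataset and cross-species
  agreement via Spearman's ρ, top-k presence overlap, joint
  presence/absence, direction-of-trend with twofold counts, and row
  z-scored heatmap matrices.
* **Power** (`de_power`, `de_sample_size`, `de_power_mc`) —
  `power = Φ(√(n·ln²Δ / (2(1/depth + cv²))) − z₁₋α/₂)` with a Monte-Carlo
  NB oracle and inverse sample-size solver.
* **Simulator** (`sim_config`, `generate_counts`) — NB counts with ground
  truth: common, twofold-DE, ganglion-exclusive, glial-contaminant and
  silent genes, asymmetric contamination admixture, matched reference
  presence set, and an ortholog comparison table with configurable
  concordance.

The package also ships the 24-gene table of ganglion-exclusive genes
(`inst/extdata/exclusive_genes.tsv`; 20 DRG-exclusive including 15
Hox-family genes, 4 TG-exclusive) used as a classification fixture.

## Worked example

Simulate an experiment with 20% glial admixture and run the full pipeline:

```r
library(gangliaDE)
cfg <- sim_config(n_genes = 2000, contamination_fraction = 0.2, seed = 20)
rep <- run_pipeline(sim = cfg)
print(rep)
#> gangliaDE pipeline report (v0.1.0)
#>   genes detected in either condition: 1800
#>   significant neuronal DE genes: 187 (up_a 29, up_b 38, exclusive_a 60, exclusive_b 60)
#>   significant genes excluded (not expressed / non-neuronal): 29
#>   trend concordance: 0.845 over 187 mapped genes
#>   Spearman rho vs comparison dataset: 0.284
```

1800 of 2000 genes pass the presence call (the 200 silent genes fail, as do
glial genes in the cleaner condition at low admixture — here all 80 glial
genes are rescued into detection by contamination). Of the significant
genes, 187 survive both screens: the 120 truly exclusive genes are recovered
exactly (60 + 60), and all 29 glial contaminants that reached significance
were removed by the reference screen, none promoted to "exclusive":

```r
rep$classification_summary$counts
#>          up_a          up_b   exclusive_a   exclusive_b        common
#>            29            38            60            60          1784
#> not_expressed  non_neuronal
#>             0            29
```

Exclusive genes appear as large finite fold changes (log2fc ≈ ±12 via the
zero-group pseudo-count), at the top of the DE table:

```r
head(rep$de[order(rep$de$padj),
            c("symbol", "base_mean", "log2fc", "pvalue", "padj")], 3)
#>    symbol base_mean log2fc   pvalue     padj
#>   Sim1700       697   11.8 8.36e-36 1.67e-32
#>   Sim1682       696   11.8 8.23e-35 8.23e-32
#>   Sim1673       542   11.4 5.89e-34 2.95e-31
```

Power planning for a twofold change at depth 50, CV 0.4:

```r
de_power(depth = 50, cv = 0.4, effect = 2, n = 5)
#> [1] 0.7334376
de_sample_size(depth = 50, cv = 0.4, effect = 2, power = 0.9)
#> [1] 8
```

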