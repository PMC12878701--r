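# nichefate

Spatial-niche quantification for high-definition spatial transcriptomics
of fibrotic lung disease: who is this for, and what does it compute?

Fibrotic interstitial lung diseases diverge in outcome — organising
pneumonia (OP) typically resolves under glucocorticoid (GC) therapy,
idiopathic pulmonary fibrosis (IPF) progresses despite it. A
spatially-resolved explanation is that reversible fibrosis carries a
*GC-sensitive myofibroblast state*: fibroblast spots with elevated
GC-response programme activity, coupled to apoptotic priming, embedded
in B-cell/alveolar niches. `nichefate` is an R package plus an analysis
workflow for quantifying that hypothesis on HD Visium-style data (8 µm
grid bins, donors × ROIs × spots), and a seeded synthetic cohort
generator that emulates the study design so the full pipeline is
testable end-to-end without access-controlled tissue data.

## What it computes

* **Rank-based signature scores** (UCell construction). Per spot, genes
  are ranked by decreasing expression (average ties, ranks capped at
  `rmax + 1` beyond `rmax`); for a signature of size *n* with rank sum
  *R*,

  U′ = R − n(n+1)/2,  score = max(0, 1 − U′/(n·rmax)) ∈ [0, 1].

* **GC-sensitive classification.** A spot is GC-sensitive when its
  GC-response score is at or above the within-sample 75th percentile
  (nearest-rank quantile, inclusive); a z-score rule (z ≥ 0.674) and a
  top 10–30 % sensitivity scan with donor-resampling bootstrap CIs
  (1000 replicates) probe robustness of group contrasts to the
  threshold.
* **Donor-level statistics.** ROI-weighted proportions (equal-weight
  mean of per-ROI fractions, ROIs under 10 denominator spots excluded),
  Kruskal–Wallis (chi-square, exact-enumeration and Monte Carlo
  permutation p), Dunn pooled-rank post-hoc contrasts (Holm/BH),
  Wilcoxon rank-sum (exact for small untied samples), Cliff's delta,
  donor-level Spearman correlation with bootstrap CI, BH/Holm
  adjustment, DEG threshold filtering (padj < 0.05, |log2FC| > 0.25),
  and TOST equivalence with a caller-supplied margin.
* **Spatial geometry**, strictly per ROI: cell-type centroids and their
  distances, exact nearest-neighbour distance distributions between
  cell-type populations, Gaussian kernel-density maps (Silverman
  bandwidth, 8 µm cells), and distance-ordering gradients from a
  reference population.
* **Stage-resolved OP dynamics**: composition (AT2, inflammatory
  aggregate, Fib_myo) and GC-sensitive/apoptosis coupling across
  early/middle/late ROIs.
* **Synthetic cohorts**: 4 groups (CTRL, CTD-ILD, OP, IPF) with 5/5/6/5
  donors × 3 ROIs (63 ROIs), clustered lesion niches, Dirichlet
  deconvolution-style weights, negative-binomial counts with
  signature-gene fold effects, and a hierarchical Gaussian copula
  planting a chosen Spearman correlation between the GC-response and
  apoptosis programmes.

## Worked example

```r
library(nichefate)

cfg    <- cohort_config(seed = 20260927)   # the study design, all defaults
cohort <- generate_cohort(cfg)
cohort
#> synthetic_cohort: 16128 spots, 63 ROIs, 21 donors, 4 groups, 240 genes

scores <- ucell_score(cohort$counts, gene_panel(cfg)$signature_genes,
                      rmax = nrow(cohort$counts))
labels <- assign_labels(cohort$weights)
cls    <- classify_gc(scores, cohort$spot_table,
                      gc_threshold_rule(percentile = 75), labels = labels)
donors <- roi_weighted_proportion(cls, cohort$spot_table, labels,
                                  numerator = "Fib_myo",
                                  denominator = "Fib_myo")
aggregate(value ~ group, donors, median)
#>     group     value
#> 1 CTD-ILD 0.2437562
#> 2    CTRL 0.2697209
#> 3     IPF 0.2228698
#> 4      OP 0.4699267

kw <- kruskal_wallis(donors$value, donors$group, n_perm = 9999)
kw[c("statistic", "p_value", "p_perm")]
#> $statistic  13.89351
#> $p_value    0.003053751
#> $p_perm     4e-04
```

The default cohort plants a 3-fold GC-response elevation in OP
myofibroblast spots: OP donors carry roughly twice the GC-sensitive
Fib_myo fraction of every other group (0.47 vs 0.22–0.27 medians), and
the donor-level Kruskal–Wallis rejects group exchangeability. The
planted Spearman-0.6 coupling of the GC and apoptosis programmes shows
up at the donor level (`analysis/02_score_classify.R`) as

```
donor-level Spearman GC vs apoptosis (Fib_myo):
  rho = 0.849, 95% CI [0.575, 0.946], p = 1.12e-06
```

## Analysis workflow

Numbered drivers under `analysis/` run the full narrative on the
simulated study cohort and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_cohort.R` | simulate and write the study-design cohort |
| `02_score_classify.R` | signature scores, GC-sensitive classification, donor-level group tests, GC–apoptosis correlation |
| `03_proximity.R` | B-cell→Fib_myo distances, centroids, density map, gradient |
| `04_sensitivity_scan.R` | top 10–30 % + z-score threshold scan with bootstrap CIs |
| `05_stage_dynamics.R` | stage-resolved composition and GC/apoptosis dynamics |
| `06_calibration_recovery.R` | null calibration and parameter-recovery simulations |

Run them in order from the repository root (`Rscript analysis/01_…`).

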