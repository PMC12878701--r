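---
title: "Quantifying glucocorticoid-sensitive niches in spatial transcriptomics of fibrotic lung disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glucocorticoid-sensitive niches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichefate)
```

## The scientific problem

Fibrotic interstitial lung diseases differ sharply in whether their
fibrosis can resolve. Organising pneumonia (OP) typically reverses under
glucocorticoid (GC) therapy; idiopathic pulmonary fibrosis (IPF)
progresses despite it; connective-tissue-disease-associated ILD
(CTD-ILD) sits between. A spatial-transcriptomic view of this contrast
treats the tissue as a mosaic of *niches*: local neighbourhoods of
myofibroblasts, immune cells and epithelium whose composition and
signalling state differ by disease. The hypothesis the pipeline is built
to quantify is that reversible fibrosis carries a *GC-sensitive*
myofibroblast state — fibroblast spots with high GC-response programme
activity, coupled to apoptotic priming and embedded in B-cell/alveolar
niches — while progressive fibrosis does not.

`nichefate` implements the quantitative core of that analysis for
high-definition spatial transcriptomics (8 µm grid bins, called *spots*),
organised as donors × regions of interest (ROIs; disjoint annotated
tissue fields, three per donor) × spots. Every inferential statement is
made at the donor level.

## The measurement chain

### Rank-based signature scoring

Per-spot programme activity is scored with a capped Mann–Whitney
statistic on expression ranks (the UCell construction). Within each
spot, genes are ranked by decreasing expression with average ranks for
ties; ranks above a cap `rmax` are set to `rmax + 1` (genes missing from
the matrix are treated the same and reported). For a signature of size
$n$ with rank sum $R$,

$$U' = R - \frac{n(n+1)}{2}, \qquad
s = \max\!\left(0,\; 1 - \frac{U'}{n \cdot r_{\max}}\right) \in [0,1].$$

The score is 1 exactly when the signature occupies the top $n$ ranks and
sits at the floor $(n-1)/(2\,r_{\max})$ — zero for practical purposes —
when every signature gene is capped. Because it is purely rank-based the
score is invariant under any strictly increasing transform of a spot's
expression vector, so no normalisation of counts is required before
scoring. `rmax` defaults to 1500; for small simulated panels the
pipeline passes the panel size instead so that the cap binds the same
way it does on a transcriptome.

### Discrete labels from deconvolution weights

Cell-type weights per spot (as produced by reference-based
deconvolution, e.g. RCTD) are consumed, never computed. The discrete
label is the argmax cell type when its weight reaches `min_weight`
(default 0.4, configurable), else the reserved label `"unknown"`; exact
ties break lexicographically, with a warning. The cutoff is not reported
by the source analyses; 0.4 keeps the unknown fraction at the per-mille
level on the synthetic cohorts, the same order reported for the real
data.

### GC-sensitive classification

A spot is GC-sensitive when its GC-response score is at or above the
within-sample 75th percentile (the top quartile). Two numerical choices
are fixed deliberately:

* **Nearest-rank quantile, inclusive flag.** The threshold is the
  `ceil(p/100 * n)`-th order statistic and spots with `score >=
  threshold` are flagged. With an interpolating quantile the flag set is
  ambiguous under ties; with nearest-rank it is exactly the top-$k$
  order statistics, and the flagged fraction converges to 25 % with a
  $1/n$ granularity error.
* **Per-sample scope.** Thresholds are computed within each donor
  (configurable to ROI), which removes cross-sample scale differences.

A consequence worth stating explicitly: if the threshold pool *equals*
the population whose flagged fraction is the statistic, the per-sample
percentile flags a fixed 25 % of it in every donor and group contrasts
degenerate by construction. Group contrasts therefore compute the
threshold over a broader pool — by default all scored spots of the
sample — and then take the flagged fraction *within* the fibroblast
population. `classify_gc()` itself supports both orders via
`restrict_to`; the scan and pipeline defaults use the broad pool. Scope
units with fewer than 4 spots are flagged unreliable (not dropped); an
all-tied unit saturates (every spot at or above the threshold) and is
marked degenerate. The alternative z-score rule standardises within
scope and flags $z \ge 0.674$, the upper-quartile equivalent under
normality — the comparable default where no cutoff is prescribed.

### Donor-level statistics

The donor statistic for proportions is ROI-weighted: per ROI the flagged
fraction among denominator spots, then the equal-weight mean over the
donor's ROIs with at least `min_spots` (default 10) denominator spots.
Equal ROI weight matches the balanced three-ROIs-per-donor design;
excluded ROIs and donors are reported, never silently dropped. A
pooled-spots alternative exists behind the same interface.

Hypothesis testing is nonparametric throughout: Kruskal–Wallis across
groups, Dunn's pooled-rank z post-hoc contrasts (Holm or BH adjusted,
per analysis), Wilcoxon rank-sum for two-group contrasts (exact when
`min(n, m) <= 8` without ties), Cliff's delta as the effect size, and
donor-level Spearman correlation with a donor-resampling percentile
bootstrap CI (1000 replicates, 95 %). Exact small-sample routes are
built in: full enumeration of group assignments for Kruskal–Wallis at
$N \le 12$ and of rank permutations for Spearman at $n \le 7$.

One calibration subtlety: the chi-square approximation to the
Kruskal–Wallis p is noticeably conservative at donor-scale cohorts — at
the 5/5/6/5 layout its true level is ≈ 0.038 for nominal 0.05 (measured
at 50 000 null replications). `kruskal_wallis()` therefore also offers a
seeded Monte Carlo permutation p (`n_perm`), which is exact-level by
construction; the calibration experiment reports the permutation route
and shows 0.049–0.059 empirical type-I across seeds at 2000
replications. The chi-square p remains the default `p_value` because it
is what the field's standard tooling reports.

Equivalence testing between cohorts is a TOST built from two one-sided
Wilcoxon tests against ±margin on pooled-SD-standardised values. The
margin has no default: it is a substantive choice the caller must make,
and the result records it.

### Spatial geometry

All geometry is strictly per-ROI — ROIs are disjoint tissue fields and
cross-ROI distances are meaningless. Provided are (i) cell-type
centroids and their distance matrices; (ii) per-spot nearest-neighbour
distance distributions between two populations (with self-exclusion when
source and target coincide), exact by construction (vectorised
cross-distance blocks, no approximate index); (iii) Gaussian
kernel-density maps over the ROI bounding box padded by three
bandwidths, cell size 8 µm, bandwidth per axis by Silverman's rule
unless fixed, renormalised to unit in-grid mass with the raw mass kept
as metadata; and (iv) distance-ordering gradients from a reference
population (ascending ranks, average ties). Centroid distances and NN
distributions answer different questions — aggregate repositioning
versus per-spot proximity — and both are exposed behind one interface.

### Stage-resolved dynamics

OP ROIs carry consumed (never inferred) stage labels — early
inflammatory, middle fibro-inflammatory, late fibrotic. Per (donor,
stage): equal-ROI-weight composition proportions (AT2; the inflammatory
aggregate = macrophages + lymphocytes + neutrophils; Fib_myo) among
confidently labelled spots, and the GC-sensitive Fib_myo fraction
(donor-stage cells under 10 Fib_myo spots excluded, reported). The
apoptosis coupling contrasts GC-sensitive versus GC-low Fib_myo spots by
Wilcoxon with BH adjustment across stages plus Cliff's delta. A caveat
the defaults accept: donors contribute ROIs to several stages, so
(donor, stage) means are not fully independent observations across
stages; the tests treat them as such, which is the same design the
source analyses use.

## The synthetic cohort generator

Real accession-controlled tissue data cannot ship with a pipeline; the
generator exists so every stage is testable end-to-end under known
truth. Its defaults *are* the study design: groups CTRL / CTD-ILD / OP /
IPF with 5/5/6/5 donors, three ROIs each (63 ROIs), square lattices at
8 µm pitch, and group composition priors encoding the qualitative
structure (fibroblast/B-cell-rich OP, bronchiolised IPF, macrophage-rich
CTD-ILD, epithelial/endothelial-rich controls).

* **Niches.** Lesions are Poisson-many Gaussian-radius centres per ROI;
  composition blends from the group prior to a fibroblast-rich override
  by distance to the nearest centre. Niches can be restricted to chosen
  groups to plant group-specific co-clustering (e.g. B-cells joining the
  lesion in OP only).
* **Weights.** Deconvolution-style weights are Dirichlet draws pulled
  towards the true label, with concentration set so roughly 0.1 % of
  spots fall below the default confidence cutoff — the order of the
  unknown rate reported for real deconvolution.
* **Counts.** Negative binomial with shared baseline mean (default 1
  per gene per spot, dispersion 0.5 — sparse, HD-bin-like counts);
  signature-gene means are multiplied by `1 + (fold - 1) * activity`
  where activity is the spot's latent programme level in [0, 1].
* **Panel.** Eight genes per signature over five programmes plus 200
  background genes. The background panel matters: with tiny panels, two
  positively coupled programmes *compete for ranks* inside each spot and
  the mechanical negative coupling materially attenuates a planted
  donor-level correlation. Two hundred background genes restore the
  real-transcriptome regime in which a signature is a negligible rank
  fraction.
* **Correlation planting.** The GC-response and apoptosis programmes are
  coupled through a hierarchical Gaussian copula: latent normals
  $z = \sqrt{w}\,u_{\text{donor}} + \sqrt{1-w}\,e_{\text{spot}}$ with
  the same Pearson parameter $2\sin(\pi\rho/6)$ at both levels, so the
  spot-level Spearman correlation is exactly the target ρ and donor mean
  activities inherit the same coupling. The donor share $w$ (default
  0.5) is what makes the planted ρ measurable by a donor-level
  correlation analysis — donors genuinely differ in programme activity.
  Setting $w = 0$ recovers a flat spot-level copula.
* **Stages.** OP ROIs are staged by largest-remainder apportionment of
  the configured fractions within each donor (with three ROIs and equal
  thirds, each OP donor contributes one ROI per stage). Stage-specific
  composition overrides and stage-restricted effects plant the
  composition and GC dynamics.
* **Determinism.** One master seed; per-ROI and per-donor substreams are
  derived arithmetically, so identical configs are bit-identical and
  ROIs are reproducible independently of generation order.

What the generator does **not** emulate — and hence what passing tests
do not certify about real data: within-ROI spatial autocorrelation of
expression beyond niche composition, library-size and capture-efficiency
gradients, segmentation/alignment artefacts, donor-level batch effects,
bleed-over between adjacent bins, and a realistic fibroblast sub-lineage
structure (one Fib_myo label stands for the fibroblast population of
interest). Parameter-recovery results show the pipeline detects what was
planted under the stated noise model, not that the biological findings
are reproduced.

## Simulation experiments and problem sizes

The packaged experiments (also reported by `scripts/acceptance.R`) use
these sizes, chosen to make each measurement well-powered while keeping
a full run in minutes on one core:

* Classification rate: 21 samples × 1000 tie-free uniform scores.
* Null calibration: 2000 Kruskal–Wallis replications at the 5/5/6/5
  layout (399 label permutations each); 500 bootstrap-coverage
  replications at n = 30 donors, 1000 resamples each.
* OP recovery: 100 cohorts, 22 × 22-bin ROIs (so OP donors carry ~500+
  fibroblast spots), a 2-fold GC effect in OP Fib_myo only; success =
  OP's median donor-level GC-sensitive Fib_myo proportion exceeds every
  other group's median.
* Middle-stage recovery: 100 OP-only cohorts with the effect restricted
  to middle-stage ROIs; success = middle median above early and late.
* Correlation recovery: 100 cohorts with 3-fold GC and apoptosis
  effects in Fib_myo of all groups and planted ρ = 0.6; success = the
  donor-resampling bootstrap CI covers 0.6. The mean recovered ρ sits
  slightly below the target (≈ 0.51–0.55) — residual attenuation from
  count noise on the score scale — which is why coverage, not the point
  estimate, is the criterion.
* Threshold-scan robustness: one cohort with the default 3-fold OP
  effect; the OP−IPF contrast and its bootstrap CI at top-10/15/20/25/30
  percentiles and the z-score rule.

## Known limitations

* The percentile rule conditions on the sample's own score
  distribution; it measures *relative* GC-programme elevation, not an
  absolute activity level, and cannot compare absolute programme
  strength across cohorts.
* Dunn contrasts use the normal approximation; at very small group
  sizes the Wilcoxon route (exact) is preferable and available.
* The bootstrap resamples donors only. ROI- or spot-level resampling
  would capture within-donor uncertainty but break the donor-level
  inference contract; it is deliberately not offered.
* `filter_degs()` consumes an externally fitted differential-expression
  table; no expression model is fitted here.
* Stage comparisons inherit the donor-overlap dependence noted above.
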