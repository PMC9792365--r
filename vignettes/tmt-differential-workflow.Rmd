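---
title: "Multi-batch TMT differential expression: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-batch TMT differential expression: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtdiff)
library(dplyr)
```

# The problem

Isobaric labelling (TMT) quantifies up to eleven samples per mass-spectrometry
run through reporter-ion intensities, but a cohort of thirty subjects needs
several runs ("batches"), and reporter intensities are only comparable within
a run. The standard remedy is a *master pool* (MP): an aliquot pooled from all
biological samples, labelled in one channel of every batch. Dividing each
sample's intensities by the same-batch MP converts them to relative
abundances on a shared scale; residual batch structure is then removed with
an empirical-Bayes location/scale adjustment.

tmtdiff implements that normalization cascade together with two
complementary differential tests — a SAM-style moderated t-statistic with
permutation q-values, and a bootstrap ROC/AUC statistic with a sorted-ratio
permutation q-value — plus over-representation analysis of the selected
proteins and the noncentral-t power calculation used to size such a study.
A synthetic-data generator with known ground truth makes every stage
testable without any external download.

# The normalization cascade

The pipeline order is fixed and enforced (each verb checks the step history
carried on the table):

1. `reference_normalize()` — divide by the same-batch MP, per protein. Any
   multiplicative batch effect shared by samples and pool cancels exactly
   here. Zero intensities are treated as missing on input (a reporter
   signal-to-noise of 0 is non-detection); a missing MP value blanks the
   protein for that whole batch.
2. `median_center()` — divide each protein by its median over observed
   biological samples, putting every protein's median relative abundance
   at 1. Fold changes (`fold_change()`) are computed at this stage, on the
   linear scale.
3. `log2_zscore()` — log2, then standardize each *sample column* to mean 0,
   SD 1 over its observed entries. The sample-SD convention (denominator
   n − 1) is used and fixed. Z-scoring per sample is the default literal
   reading of per-sample standardization; per-protein z-scoring is available
   via `by = "protein"` for comparability with protein-wise summaries.
4. `drop_missing()` — keep exactly the proteins observed in every biological
   sample. Downstream statistics assume a complete matrix.
5. `combat_adjust()` — parametric empirical-Bayes batch correction
   (below).

# Batch correction and its diagnostics

`combat_adjust()` fits, per protein, a linear model with batch indicators
(optionally plus the case/control covariate), standardizes the residual
scale, estimates per-batch location γ and scale δ² per protein, and shrinks
them across proteins towards method-of-moments parametric priors (Normal for
γ, inverse-gamma for δ²) with the standard iterative conditional-posterior
update, stopping when the largest relative change drops below `tol`
(default 1e-4). The shrunken effects are removed and the grand mean and
covariate structure restored. All fitted parameters, priors and iteration
counts are returned via `batch_params()`.

Two consequences of the shrinkage are worth knowing:

* **The adjustment is not exactly idempotent.** Batch moments estimated from
  finite data are noisy; shrinkage removes only part of each estimate, so a
  second application still changes values (by roughly half the remaining
  residual, a contraction towards a batch-free fixed point). Tests assert the
  contraction, not exact idempotence.
* **Only the centred shift is estimable.** The model removes a per-protein
  grand mean, so recovery of simulated batch shifts is judged against
  γ centred per protein, on the standardized scale.

`batch_pca()` provides the before/after diagnostic: samples projected on the
first two principal components, scored by the mean silhouette width of the
batch labels (near 0 or negative = batches intermixed). On data carrying an
additive batch shift the silhouette drops markedly after correction; in the
full synthetic pipeline the MP division already cancels the additive shift,
so the before/after contrast is demonstrated on directly constructed
batch-shifted matrices (entered with `as_normalized()`).

## Why the group covariate is *not* protected by default

Classic practice passes the biological contrast as a covariate so the batch
model cannot absorb it. With this study design that protection is
unnecessary and measurably harmful:

* The design is batch-balanced (each batch holds equally many cases and
  controls), so the case/control contrast is numerically preserved by the
  unprotected adjustment — batch means contain the group effect equally and
  subtracting them leaves the contrast intact.
* Protecting the contrast re-inserts the *observed* labelling's group
  difference exactly while the residuals around it are shrunk. The observed
  labelling thereby becomes special: label permutations are no longer
  exchangeable with it, and the downstream permutation FDR becomes
  anti-conservative. On global-null simulations (1000 proteins, 15 vs 15,
  20+ seeds) the SAM procedure at q < 0.05 selected at least one (false)
  protein in ~10% of datasets with protection versus ~2% without.

`protect_group = TRUE` remains available for unbalanced designs, where the
trade-off reverses.

# The SAM permutation test

`sam()` computes, per protein, `d = (mean_case − mean_control) / (s + s0)`
with `s` the pooled standard error and `s0` a small stabilization constant
(default 0.1, a conventional volcano-plot choice; it is echoed in the result
attributes because the selection depends on it). For each threshold |d| the
q-value is

    q(|d|) = mean over permutations of #{ |d*| >= |d| } / #{ observed |d| >= |d| }

clipped to [0, 1] and monotonized by a running minimum from the largest |d|
downward. Significance is `q < q_threshold` (default 0.05), which is
equivalent to |d| at or above an attained cutoff; `volcano_boundary()`
converts that cutoff into the curved significance boundary of the volcano
plot (flat when `s0 = 0`).

**Permutations are stratified by batch**: every permutation reassigns
case/control labels within each batch, preserving the per-batch group
counts. Unrestricted permutations are subtly wrong after batch correction —
the observed labelling is batch-balanced and the corrected matrix has had
batch moments estimated and removed, so unbalanced relabellings are not
exchangeable with it (measured as a ~10–13% null any-selection rate versus
~2% stratified). When the number of distinct stratified assignments does not
exceed `n_permutations`, they are enumerated exhaustively (with a note).

The default of 250 permutations makes the smallest attainable nonzero q
granular at the 1/(250 × G) level, ample for a q = 0.05 decision at
G ≈ 1000 proteins.

# The bootstrap ROC/AUC test

`auc()` uses the Mann–Whitney identity (fraction of case/control pairs where
the case scores higher; ties count one half). `bootstrap_auc()` resamples
subjects with replacement B = 1000 times — stratified within group, keeping
the original 15 + 15 sizes — and reports the mean and SD of the resampled
AUCs. A resample with no class contrast contributes AUC 0.5.

Computationally, each bootstrap AUC is a bilinear form in the precomputed
G × (n₁·n₀) pairwise comparison tensor, with the resample's multiplicity
vectors as weights: one matrix product scores all proteins for all B
resamples. A consequence is that within a replicate the same cohort resample
scores every protein — the natural reading of resampling *subjects* — while
each protein's marginal bootstrap law is exactly the stratified
with-replacement bootstrap.

`null_bootstrap_auc()` repeats the computation under batch-stratified label
permutations (default 20), pooling all proteins' null mean AUCs with
per-permutation provenance. `bootauc_q()` then assigns q-values tail by
tail: proteins with mean AUC above 0.5 are thresholded descending, below 0.5
ascending, and at each observed value

    q = (per-permutation average count of null means at least as extreme) /
        (count of observed means at least as extreme)

clipped and monotonized towards the extremes; a mean of exactly 0.5 gets
q = 1. The ratio is oriented null-over-observed — the orientation in which
the ratio estimates a false discovery rate in [0, 1]. `rank_by_sd()` orders
results by bootstrap stability (ascending SD, ties by larger |mean − 0.5|,
then id), the ordering used to headline the most reliable markers.

`intersect_selections()` takes proteins significant under *both* procedures,
annotated up/down by the sign of the SAM mean difference.

# Enrichment

`ora()` tests a selected list against GMT gene sets (`read_gmt()` /
`write_gmt()`) with the hypergeometric upper tail (or its conservative EASE
variant, overlap reduced by one), Benjamini–Hochberg q-values across sets,
and the classic display arithmetic: `count` (overlap), `ph` (set members in
the background universe) and `percent = 100·count/ph` to one decimal. The
background defaults to the tested universe — the proteins surviving
`drop_missing()` — because that is the population the selection was drawn
from; enrichment databases' internal backgrounds differ, so external
p-values are comparable only qualitatively. `ph` can optionally display the
raw set size while the test still uses in-background membership.

# Power and design

`t_test_power()` evaluates the exact noncentral-t power of a two-sample
t-test (noncentrality (δ/σ)·√(n/2), df 2n − 2); `sample_size()` inverts it
by root finding to |power − target| < 1e-8, reporting the fractional n and
its ceiling. With δ = log2 1.5 = 0.585, σ = 0.208 (a typical residual log2
SD for TMT cohorts), two-sided α = 1e-4 and power 0.8:

```{r power}
sample_size(delta = 0.585, sigma = 0.208, alpha = 1e-4, power = 0.8)
```

about 9.4 subjects per group — the calculation behind a 15 + 15 design with
headroom. Two-sided is the default (`sides = "one"` available). The search
is bounded below at n = 2, the smallest size with a defined two-sample
t-test.

# The synthetic generator

`generate_dataset()` draws, on the log2 scale per protein: a baseline
(Normal, default mean 20, SD 2, spanning the dynamic range of reporter
summaries), a signed group effect of ±`effect_log2fc` (default
log2 1.5 = 0.585) on a `spike_fraction` (default 10%, half up half down), an
additive per-batch, per-protein shift γ ~ N(0, `batch_additive_sd`), and
residual noise N(0, `residual_sigma` = 0.208) scaled by a per-batch,
per-protein inverse-gamma variance-inflation factor (mean 1, shape
`batch_multiplicative_shape`); values are exponentiated to linear
intensities. The MP reference column of each batch is the linear-scale mean
of all biological samples' pre-noise intensities (the pool is mixed once),
shifted by that batch's γ — so MP division cancels the additive batch
effect, as in the real protocol. Missingness is MCAR on biological entries
only (default rate 2%).

Defaults not fixed by the study design were chosen once as realistic for
multi-batch TMT and then left alone: `batch_additive_sd = 0.3` log2 units (a
clearly visible but not dominating batch effect), shape 25 (≈ ±20% noise-SD
inflation), `missing_rate = 0.02`.

What the generator does *not* emulate: spectrum-level effects (co-isolation,
isotope impurity), peptide-to-protein rollup, intensity-dependent missingness
(real TMT missingness is enriched at low abundance), heavy-tailed biological
outliers, and correlated protein modules. Calibration results below therefore
speak to the *procedures* under the generating model, not to every property
of real data.

# Calibration results and problem sizes

All of the following are computed by the test suite / acceptance script,
at these problem sizes (chosen to give stable Monte-Carlo estimates at
interactive runtimes):

* **Null FDR.** On 20 seeded global-null datasets (1000 proteins, 15 vs 15,
  σ = 0.208), both q-value procedures at q < 0.05 fire in at most the
  binomial-95% number of seeds expected at a true 5% rate; the mean
  per-dataset false-discovery proportion is ≈ 0–0.05. Under a global null
  the per-dataset FDP is all-or-nothing (any selection is false), so the
  mean FDP estimates the probability of any false selection — the FDR
  definition E[V/max(R, 1)] applied seed-wise.
* **Power.** With 10% spikes at ±0.585 and σ = 0.208, n = 15/15 — the
  regime the 9.4-per-group design targets — the SAM selection at q < 0.05
  recovers spiked proteins with empirical power ≥ 0.8 (observed ≈ 1.0) at
  realized FDP ≈ 0.04.
* **Oracles.** AUC equals brute-force pair enumeration on 1000 random small
  instances; hypergeometric p-values match exhaustive tail enumeration for
  all universes N ≤ 12; batch-location recovery correlates r > 0.9 with
  centred truth at 1000 proteins; the batch-correction silhouette decreases
  in ≥ 19 of 20 batch-shifted replicates.

# Numerical conventions and degenerate inputs

* Zero-variance proteins in the t-test: equal means give t = 0, p = 1;
  unequal means give |t| = ∞, p = 0.
* A protein row that is entirely missing passes through `median_center()`
  unchanged and flagged; it is removed at `drop_missing()`.
* A constant sample column (or protein row, with `by = "protein"`) makes the
  z-score undefined and raises a transform error naming it.
* Ties in AUC are midranked (0.5 per tied pair); an all-tied resample is
  AUC 0.5.
* `q` monotonization is a running minimum from the most extreme statistic
  inward, so q never decreases as a threshold relaxes.
* Every stochastic stage takes an explicit seed; `run_pipeline()` derives
  per-stage seeds deterministically from one global seed, and RNG state is
  restored after each call.
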