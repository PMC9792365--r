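# tmtdiff

Differential protein expression for multi-batch TMT (tandem mass tag)
proteomics, as a tidyverse-style R package. It implements the full
statistical workflow of a case/control cohort quantified in several
isobaric-labelling batches:

* **Normalization cascade** — division by the master-pool (MP) reference
  channel of each batch, per-protein median centring, log2 + per-sample
  z-scoring, removal of proteins with any missing value, and parametric
  empirical-Bayes batch correction (location + scale, Normal/inverse-gamma
  priors) with a PCA + silhouette batch diagnostic.
* **Dual differential testing** — a SAM-style moderated t-statistic
  `d = (x̄_case − x̄_control)/(s + s0)` with batch-stratified permutation
  q-values, and a bootstrap ROC/AUC statistic (mean ± SD of AUC over B
  resamples with replacement) with a sorted-ratio permutation q-value;
  proteins significant under **both** at q < 0.05 form the final set.
* **Enrichment** — hypergeometric/EASE over-representation analysis against
  GMT gene sets, with the classic Count / PH / Percent table arithmetic and
  Benjamini–Hochberg q-values.
* **Design** — exact noncentral-t power and sample-size calculation for a
  two-sample t-test: power at per-group size n has noncentrality
  (δ/σ)·√(n/2) and df 2n − 2.
* **Synthetic data** — a generator that emulates the design (3 batches of
  11 channels, one MP channel each, 15 + 15 subjects, log-normal
  intensities, ±log2 1.5 spiked effects at residual σ = 0.208, additive and
  multiplicative batch effects, MCAR missingness) with ground truth, so
  every stage is testable offline and calibration (FDR, power) is
  measurable.

It is written for proteomics analysts and methods developers who want the
whole pipeline reproducible, seeded and testable, rather than spread across
interactive tools.

## Worked example

How many subjects per group does the design need to see a 1.5-fold change
(δ = log2 1.5 = 0.585) at residual log2-scale SD σ = 0.208, two-sided
α = 1e-4, power 0.8?

```r
library(tmtdiff)
sample_size(delta = 0.585, sigma = 0.208, alpha = 1e-4, power = 0.8)
#> # A tibble: 1 × 8
#>       n n_ceiling achieved_power delta sigma  alpha target_power sides
#>   <dbl>     <dbl>          <dbl> <dbl> <dbl>  <dbl>        <dbl> <chr>
#> 1  9.40        10          0.800 0.585 0.208 0.0001          0.8 two
```

9.4 per group — so a 15 + 15 cohort has comfortable headroom. Run the whole
pipeline on synthetic data with that design:

```r
cfg <- run_config(
  synthetic = synthetic_config(n_proteins = 1000, seed = 101),
  sam     = list(n_permutations = 250),
  bootauc = list(B = 500, n_permutations = 20),
  seed    = 101)
run <- run_pipeline(cfg)
run
#> <tmt_run> 1000 proteins in, 545 tested
#>   SAM significant: 56; bootstrap-AUC significant: 57; common: 56
#>   batch silhouette: -0.113 -> -0.108
```

1000 simulated proteins enter; 545 survive the missing-value filter (2%
MCAR missingness across 30 samples keeps ≈ 0.98³⁰ ≈ 55%). The SAM and
bootstrap-AUC procedures each select ~56 proteins at q < 0.05 and agree on
56. The batch silhouette is already ≈ 0 before correction because MP
division cancels the shared additive batch shift in this generator.

```r
head(dplyr::arrange(tidy(run), q_sam, p), 4)
#>   protein mean_diff fold_change log2fc     t        p     d q_sam ...
#> 1 P00242       2.79       1.58   0.660  13.2 1.67e-13  8.94     0
#> 2 P00679      -3.07       0.610 -0.713 -12.5 5.63e-13 -8.88     0
#> 3 P00982       2.59       1.52   0.603  12.1 1.34e-12  8.22     0
#> 4 P00091       3.03       1.64   0.718  11.0 1.03e-11  8.09     0
```

The top hits have fold changes ≈ 1.5 (or its reciprocal) — the spiked
effect size. Scoring the final set against the generator's ground truth:

```r
evaluate_selection(run$intersection$protein, run$truth)
#>   true_positives false_positives true_negatives false_negatives empirical_fdr
#> 1             53              3             897              47        0.0536
```

53 of the 100 spiked proteins are recovered at an empirical FDR ≈ 0.05;
almost all 47 misses were removed by the missing-value filter before
testing (only ~55 spiked proteins were tested), so power among *tested*
proteins is ≈ 0.97.

Plots: `autoplot(run$sam)` (volcano with the q = 0.05 boundary curve),
`autoplot(run$bootauc)` (mean AUC vs SD), `autoplot(run$pca$before)` /
`autoplot(run$pca$after)`, `plot_enrichment(run$enrichment)`.

A thin CLI over the same functions lives in `inst/scripts/tmtdiff.R`
(`power`, `simulate`, `run` subcommands).

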