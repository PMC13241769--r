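# netsig

Spectral and network-topology signatures of resting-state EEG, for the
clinical question of drug-resistant epilepsy (DRE): does a patient's
resting-state quantitative EEG (qEEG) carry a signature of drug resistance,
and does that signature add diagnostic value over the usual clinical
predictors?

The package implements the full analysis chain as composable, seeded,
tidyverse-style functions:

* **Preprocessing** — common average reference, zero-phase FIR band-pass
  (0.5–70 Hz) with a 50 Hz notch, selection of 180 ± 25 s of artifact-free
  epochs (EDF/EDF+ and CSV readers included).
* **Spectral features** — Welch PSD (2 s Hann windows, 50% overlap),
  relative band power in δ (2–4), θ (5–7), α (8–12), β (13–29) Hz, and the
  aperiodic component of the spectrum via a robust log–log fit:
  exponent χ (slope) and offset, with the α window excluded.
* **Connectivity** — band-wise weighted phase lag index,
  `wPLI = |E Im S_ij| / E |Im S_ij|`, insensitive to zero-lag (volume
  conducted) coupling; global wPLI per band.
* **Network topology** — wPLI matrices binarized to the top 5% of edges
  (9 edges on 19 channels), then modularity Q, small-world index
  `SWI = (C/C_rand)/(λ/λ_rand)` against degree-preserving nulls,
  betweenness centrality BtwC, global efficiency gE, clustering C and
  characteristic path length λ.
* **Statistics** — two-sample permutation tests (10 000 iterations,
  most-frequent-p stabilization over 100 repeats), χ² for categorical
  tables, split-plot Band × Group ANOVA with Greenhouse–Geisser, Mauchly
  and Bartlett diagnostics, Benjamini–Hochberg FDR, channel-wise
  permutation maps.
* **Classification** — maximum-likelihood logistic regression under
  stratified 5-fold cross-validation; ROC/AUC plus Sens, Spec, PPV, NPV,
  Acc and F1; a permutation comparison of the clinical-only model
  (REG_qEEG−) against the clinical+qEEG model (REG_qEEG+).
* **Synthetic cohorts** — a fully seeded generator (1/f background,
  narrowband oscillations, lagged coupling on designed 9-edge backbones,
  zero-lag mixing, matched clinical covariates) with complete ground truth,
  used by the whole validation suite.

The DRE-like signature the pipeline is validated against: higher δ and lower
α relative power, a more negative spectral exponent, and a δ-band network
that is less integrated and more segregated — lower gE, lower SWI, higher
BtwC — than in treatment responders.

## Worked example

Generate a small synthetic cohort (10 subjects per group, 60 s recordings —
the validation default is 60 per group at 180 s), extract the feature table,
test the group contrast and compare the classification models:

```r
library(netsig)

cfg      <- cohort_config(n_per_group = 10, duration = 60, seed = 42)
features <- run_extract(cfg, seed = 1)
clinical <- gen_clinical(cfg)
features
#> # A tibble: 2,960 × 6
#>    subject_id metric    band  scope   channel   value
#>    <chr>      <chr>     <chr> <chr>   <chr>     <dbl>
#>  1 S001       rel_power delta channel Fp1     0.458
#>  2 S001       rel_power theta channel Fp1     0.00552
#>  3 S001       rel_power alpha channel Fp1     0.488
#>  ...

st <- run_stats(features, clinical, n_perm = 2000, n_repeats = 20, seed = 2)
st
#> <netsig_stats> 34 features tested (9 significant after BH at q = 0.05)
#>      metric  band mean_dre mean_ctrl statistic     p   p_adj rejected
#> 1 rel_power alpha  0.52440   0.76880 -0.244394 0.000 0.00000     TRUE
#> 3 rel_power delta  0.41445   0.15251  0.261935 0.000 0.00000     TRUE
#> 5  exponent  <NA> -2.47397  -1.76785 -0.706125 0.000 0.00000     TRUE
#> 8      btwc delta  0.02460   0.01314  0.011455 0.003 0.01275     TRUE
#> ...

clf <- run_classify(features, clinical, k = 5, n_perm = 1000, seed = 3)
clf
#> <netsig_classify> AUC clinical-only 0.900 +/- 0.224 | clinical+qEEG 1.000 +/- 0.000 | delta p = 0.03297
#> top saliences:
#>           feature  beta abs_beta     p
#> 1        exponent -2.79     2.79 0.974
#> 2 rel_power_delta  2.74     2.74 0.975
#> 3 rel_power_alpha -2.60     2.60 0.976
```

Reading this output: the DRE-like group shows the expected spectral slowing
(relative δ power 0.41 vs 0.15, α 0.52 vs 0.77, exponent −2.47 vs −1.77; all
BH-significant) and a higher δ-band betweenness; adding the qEEG block lifts
the cross-validated AUC from 0.90 to 1.00 with a permutation comparison
p = 0.033, and the salience ranking (|β| of the standardized full-data fit)
is dominated by qEEG features. At this toy size some topology metrics
(e.g. δ-SWI) are not yet significant; they are at the 60-per-group
validation scale.

`autoplot()` methods draw PSDs (`welch_psd`), wPLI heatmaps (`wpli`) and the
mean ROC curve (`crossval_roc`); `tidy()`/`glance()` methods give broom-style
summaries of ANOVA, logistic and CV objects.

A command-line wrapper over the same functions lives at `inst/cli/netsig.R`
(`simulate`, `extract`, `stats`, `classify`, `all` subcommands, YAML config).

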