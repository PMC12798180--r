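# dctprofiles

Semantic profiles and depression classification from the Demonstrative
Choice Task (DCT), for researchers studying how context-free
demonstrative choice ("this" vs "that", plus a medial form in three-term
languages) reflects psychological proximity to concepts, and whether
those choices carry signal about depression symptom severity across
languages.

## What it computes

The core statistic is the per-subject **semantic profile**. Each task
item *i* carries scores *b<sub>ij</sub>* on the 65 Binder semantic
dimensions (Sad, Fearful, Social, Vision, ...); each choice is coded
*r<sub>si</sub>* = +1 (proximal), 0 (medial) or −1 (distal); and a
subject's score on feature *j* is the response-weighted mean

&nbsp;&nbsp;&nbsp;&nbsp;P<sub>sj</sub> = (1/n) Σ<sub>i</sub> r<sub>si</sub> b<sub>ij</sub>,&nbsp;&nbsp;&nbsp;&nbsp;P = R B / n,

positive when the subject favors the proximal form for items high in
feature *j*. Around this the package provides:

* **quality control** for online responding (strict rules: >10% of
  responses under 300 ms, normalized response entropy < 0.80, >3 of 15
  failed attention checks, missing data),
* **classification** of PHQ-9 depression group (sum ≥ 10) from the
  65-dimensional profiles: stratified 70/30/validation splits, majority
  class downsampling (chance accuracy 0.5), five tuned candidates
  (ridge-penalized logistic, k-NN, boosted-tree ensemble, 2- and
  3-layer networks), label-shuffled baselines, per-language evaluation,
* **interpretation**: exact TreeSHAP feature effects with bootstrapped
  robustness (re-drawn splits), Spearman rank correlations and
  hierarchical clustering of effects across language models,
* **embedding-to-norm extrapolation** of Binder scores for unrated
  items, with a six-candidate mapping roster selected by mean R²,
* a **PCA + logistic replication arm** on the raw word-level response
  matrix with back-projected most-predictive words, and
* a **synthetic cohort generator** (seven languages, 290 items, ~34%
  prevalence, planted negative-affect effects, injectable low-effort
  responders) so the entire pipeline is testable without human data.

## Worked example

```r
library(dctprofiles)

spec    <- synthetic_spec(n_subjects = 600, seed = 42)   # planted effects
study   <- simulate_study(spec)
qc      <- apply_exclusions(study$subjects, study$trials)
profiles <- compute_profiles(
  recode_responses(study$trials, study$binder, "drop_medial", qc_retained(qc)),
  study$binder)

boot <- bootstrap_run(profiles, study$subjects, n_runs = 20, seed = 42)
glance(boot)
#> # A tibble: 1 × 7
#>   scope           n_runs n_failed median_f1  sd_f1 f1_q2.5 f1_q97.5
#>   <chr>            <dbl>    <int>     <dbl>  <dbl>   <dbl>    <dbl>
#> 1 crosslinguistic     20        0     0.973 0.0157   0.943    0.996

eff <- summarize_effects(boot)
head(dplyr::arrange(eff, -abs(mean_shap))[, c("feature", "mean_shap", "q2.5", "q97.5")], 8)
#>      feature mean_shap     q2.5  q97.5
#> 1   Pleasant   -1.7030 -2.47655 0.0000
#> 2      Happy   -0.4745 -2.50246 0.0000
#> 3    Benefit   -0.2770 -2.05224 0.0000
#> 4       Pain    0.1579 -0.07333 0.4958
#> 5  Biomotion    0.0471  0.00000 0.2073
#> 6  Disgusted    0.0292 -0.04538 0.1801
#> 7       Dark    0.0123 -0.00104 0.1019
#> 8 Unpleasant    0.0101 -0.02719 0.0683
```

Reading the output: no subject was excluded by QC on this clean cohort
(`sum(qc$excluded)` is 0 of 600); the boosted-tree classifier separates
the synthetic groups with median F1 0.97 across 20 re-drawn splits (the
generator's planted effects are deliberately strong — human data are far
noisier); and the effect summary recovers the planted directions: higher
profile scores on the negative-affect features (`Pain`, `Disgusted`,
`Unpleasant`) push predictions toward depression (positive mean SHAP),
while `Pleasant`, `Happy` and `Benefit` push toward control. Wide
bootstrap intervals on correlated affect features are expected: the tree
model picks one of several collinear features per run, which is exactly
why effects are bootstrapped.

`plot_model_comparison()`, `plot_feature_effects()`, `plot_bootstrap()`
and `plot_effect_heatmap()` (or `autoplot()` on the corresponding
objects) provide ggplot2 figures; `tidy()`/`glance()` methods give tidy
summaries of comparisons, bootstraps, PCA fits and replication results.

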