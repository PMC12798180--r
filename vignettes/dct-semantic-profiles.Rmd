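---
title: "Semantic profiles from the Demonstrative Choice Task: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic profiles from the Demonstrative Choice Task: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(dctprofiles)
```

## The task and the question

In the Demonstrative Choice Task (DCT) a participant sees one noun at a
time, stripped of any situational context, and must pair it with a
demonstrative form — "this book" or "that book" in a two-term language,
with a third, medial option in languages such as Spanish or Filipino.
With no physical referent to disambiguate, the choice is taken to express
*psychological proximity*: how near the concept feels to the speaker's
current mental state. Depression is accompanied by well-documented shifts
in the salience of negative and positive emotional content, so the
working hypothesis is that participants with high depression symptom
burden (PHQ-9 sum ≥ 10) choose the proximal form more often for concepts
high in negative-affect semantics, and less often for positively valenced
concepts.

This package implements the full analysis pipeline for that question:
quality control of online responses, construction of per-subject semantic
profiles, depression classification with a five-model comparison and
label-shuffled baselines, bootstrapped Shapley-value effect summaries
compared across language models, and a PCA-based replication arm on raw
word-level responses. Because no human data ship with the package, a
first-class synthetic-cohort generator reproduces the statistical
structure the analysis assumes and provides planted ground truth for
parameter-recovery tests.

## The semantic-profile statistic

Each of the 290 task items carries scores on the 65 Binder semantic
dimensions (experience-based ratings on a 0–6 scale: `Sad`, `Fearful`,
`Social`, `Vision`, …). Choices are coded on a proximal–distal axis,

$$ r_{si} = \begin{cases} +1 & \text{proximal} \\ 0 & \text{medial} \\ -1 & \text{distal,} \end{cases} $$

and a subject's profile is the response-weighted mean of item scores,
computed for every feature $j$ at once as a matrix product:

$$ P = \frac{1}{n_{\text{items}}} R B, \qquad
   P_{sj} = \frac{1}{n}\sum_{i=1}^{n} r_{si}\, b_{ij} . $$

A positive $P_{sj}$ means the subject preferred the proximal form for
items scoring high on feature $j$; zero means no proximal/distal
asymmetry. For three items with `Social` ratings 5.9, 2 and 2.5 and
responses $(+1, -1, -1)$ the `Social` score is
$(5.9 - 2 - 2.5)/3 \approx 0.47$:

```{r worked-example}
binder <- tibble::tibble(item_id = c("party", "car", "shame"),
                         Social = c(5.9, 2, 2.5),
                         Sad    = c(0.03, 0.1, 4.8))
responses <- tibble::tibble(subject_id = "A", party = 1, car = -1, shame = -1)
compute_profiles(responses, binder)
```

Three medial coding schemes are supported (`coding_scheme()`):
`drop_medial` (medial = 0, the default), `medial_as_distal` (−1) and
`medial_as_proximal` (+1). The denominator is always the full item count,
including medial-coded-zero trials under `drop_medial`; that matches the
divide-by-$n$ form of the worked example above, keeps the scale
comparable across schemes, and makes "dropping" the medial exactly a
zero contribution to the numerator. For two-term cohorts the three
schemes coincide, which the test suite checks end to end.

## Quality control

Low-effort online responding is excluded by three rules, each read
strictly from its stated wording:

* **fast responses** — more than 10% of non-check trials faster than
  300 ms (`fast_rt_fraction()`; a 29/290 subject is *not* excluded,
  30/290 is);
* **low response entropy** — Shannon entropy (base 2) of the empirical
  form distribution, normalized by $\log_2 K$ for a $K$-form system,
  below 0.80 (`response_entropy()`);
* **attention** — more than 3 of 15 failed attention checks.

Entropy is computed over demonstrative *forms*, not physical button
positions: button labels are randomized per trial, so a position-stuck
responder already shows up as a form-entropy deficit, and forms are the
behaviorally meaningful unit. Normalizing by $\log_2 K$ lets the single
0.80 floor apply to two- and three-term systems alike; whether the
original threshold was meant in raw bits for three-option languages is
not decidable from the text, and the normalized convention is this
package's documented choice. Attention-check trials are excluded from
the RT and entropy computations because they have a correct answer and
would bias both. Subjects with missing trials, PHQ-9 items or
demographics are excluded with reason `missing`.

## The synthetic cohort generator

`synthetic_spec()` fixes the study conditions; `simulate_study()` draws a
cohort. The defaults emulate the seven-language study the package
models:

* per-language included sample sizes (English 1654, German 488, Italian
  462, Spanish 492, Chinese 279, Filipino 199, Russian 307; a single
  total is spread proportionally), 290 items, 15 attention checks;
* **PHQ-9**: a latent severity $z \sim N(0,1)$ with loading 0.75 on each
  item's latent, ordinalized at thresholds $(-0.15, 0.70, 1.55)$. These
  were calibrated once against the reported marginals — ≈34% prevalence
  of sums ≥ 10, median sum 7, SD ≈ 6, attainable range 0–27 — and are
  frozen; other prevalence targets are met by shifting the thresholds
  analytically (`phq_prevalence()` integrates the exact nine-item
  convolution over the latent);
* **choices**: two-term subjects choose proximal with probability
  $\operatorname{logit}^{-1}(\alpha_s + \mathbf{x}_i^\top \beta_{g(s)})$,
  where $\mathbf{x}_i$ is the item's z-scored Binder row and
  $\beta_{g}$ a per-group 65-vector of planted log-odds weights;
  three-term subjects use a proportional-odds model with the same linear
  predictor and cutpoints $(-1.13, 0.61)$, giving roughly the observed
  37/40/23 proximal/medial/distal pattern. Subject intercepts are
  $N(\operatorname{logit}(0.52), 0.25)$ — the slight overall proximal
  preponderance, with a spread small enough that attentive subjects stay
  clear of the 0.80 entropy floor;
* **planted effects**: the default template (`default_effect_template()`)
  puts +0.5 on `Sad`, `Fearful`, `Unpleasant`, `Pain`, `Disgusted` and
  −0.5 on `Happy`, `Pleasant`, `Benefit`, `Drive`, `LowerLimb` for the
  depression group and zero for controls, matching the reported
  direction of effects and giving recovery tests a documented truth. The
  magnitude 0.5 is chosen for unambiguous recovery, not to reproduce the
  (much weaker) effect sizes of human data — synthetic cohorts are far
  more separable than real ones, and passing recovery tests shows the
  pipeline's correctness, not expected field performance;
* **Binder norms**: `generate_binder_matrix()` draws item scores in
  [0, 6] with the ten affect features loading (±0.8) on a shared latent
  valence factor, reproducing the strong multicollinearity of emotion
  norms (|r| ≳ 0.6 within the block) that motivates the tree-ensemble
  and regularized models;
* **reaction times** log-normal(log 800 ms, 0.4) — no empirical RT
  distribution is available, so these are plausible placeholders;
* **low-effort injection** (`inject_low_effort()`): fast responders get a
  quarter of RTs below 300 ms, constant responders answer one form on
  97% of trials, inattentive subjects pass checks with probability 0.30
  (attentive: 0.98). Injected ids are returned as ground truth, and the
  QC rules recover exactly that set on test cohorts.

Everything derives child seeds deterministically from one global seed
(`child_seed()`), so a spec reproduces byte-identical cohorts.

What the generator does *not* emulate: lexical content of items,
language-specific semantic shifts of translated stimuli, RT–semantics
coupling, non-Gaussian tails of some real per-feature distributions, and
cultural response-style differences. Green tests therefore certify the
machinery, not effect sizes in any human population.

## Classification pipeline

`make_split()` holds out 30% for testing and 20% of the training set for
validation, stratified by group × language. The training partition is
balanced by downsampling the majority class (`balance_by_downsampling()`),
anchoring chance accuracy at 0.5; the test set is evaluated both raw and
in a balanced view, and the balanced view is the one compared against
chance. Downsampling before splitting is available behind the
`downsample` argument, but balancing only the training partition is the
default: it preserves an honest test set while keeping the 0.5 anchor.
Profiles are z-scored with training-set statistics only
(`scale_profiles()` stores and reuses them), and `audit_no_leakage()`
asserts that test ids never enter fitting.

Five candidates are compared (`compare_models()`): an L2-penalized
logistic regression (the "ridge" model; a least-squares ridge on 0/1
labels thresholded at 0.5 is available as `ridge_ls` since the original
description is ambiguous), k-nearest neighbors (uniform or
distance weighting; the `leaf_size` grid axis is accepted for grid
compatibility — exact search makes it inert), a gradient-boosted tree
ensemble (xgboost, tuned over rounds, learning rate, depth and both L2/L1
penalties), and 2- and 3-layer feed-forward networks (hidden widths
128/64 and 128/64/32, rectified-linear hidden activations, sigmoid
output, tuned over batch size and epochs; implemented in-package with
Adam). Hyperparameters maximize validation F1 (ROC-AUC by option); ties
resolve to the earliest grid row, deterministically; the chosen
configuration is refit on the full balanced training set. Metrics come
from an explicit confusion-matrix tally plus trapezoidal ROC-AUC, with
the depression class positive. `shuffled_label_baseline()` permutes
labels within the training data only and runs the identical pipeline,
giving the empirical null.

## Effect interpretation

`compute_feature_effects()` uses exact TreeSHAP attributions of the
boosted-tree model on the hold-out test set (local additivity to the
model margin holds to float precision, which the tests assert at 1e-6).
Effects are summarized per feature by the signed mean attribution among
samples *above the feature's median score*. This orientation is the one
the directional reading requires — positive means higher scores (more
proximal choices on items high in the feature) push predictions toward
depression. The unconditioned mean over all samples is also emitted
(`mean_shap_all`), but it is not the directional summary: for any
discriminative feature it mostly reflects the class mix of the
evaluation set, and on an imbalanced test set the majority class's
negative attributions dominate it even when high scores clearly indicate
depression. Test-set (rather than all-sample) attribution is used to
match the evaluation spirit; this is a documented choice.

`bootstrap_run()` redraws the stratified 70/30 split (re-splitting
without replacement, not case resampling — "a new training and test
set"), rebalances, retrains the tuned configuration and records metrics
and effects per run; failures are recorded, never dropped.
`correlate_effects()` compares scopes by Spearman rank correlation
(Kendall by flag), and `cluster_features()` orders features by
average-linkage hierarchical clustering on Euclidean distances of the
scope × feature effect matrix — both choices are the common defaults
where the original description names only the family of method.

## Embedding-to-norm extrapolation

Task items missing from the Binder norm set get predicted scores via a
learned mapping from word-embedding space (`fit_mapping_candidates()`).
Six candidate families — ordinary least squares, ridge, k-NN regression,
per-dimension boosted trees, and 2-/3-layer networks — are trained on
norm words *outside* the task item set (the exclusion is audited
programmatically), scored by mean R² across the 65 dimensions on a
seeded 80/20 held-out split, and the best mean R² wins. The exact
candidate hyperparameters of the original roster are not printed in the
main text, so the roster is configurable and the shipped one is a
documented approximation. Tests use `generate_embedding_fixture()`,
synthetic Gaussian vectors with a planted linear norm map, so recovery
has a closed-form truth; real embedding files (`read_embeddings()`, the
common word-per-line text dialect) are an optional input, never required.

## Replication arm

`fit_pca()` + `fit_variants()` re-run the word-level analysis: centered
PCA of the subjects × words response matrix (components retained to 90%
cumulative variance by default — the original count is not printed),
then logistic regression in four variants (`mDCT`, `mDCT+GenderAge`,
`mGenderAge`, `mRandomBaseline`) with bootstrap accuracy summaries over
re-drawn splits. Gender enters one-hot against the largest category;
age is z-scored with training statistics. Accuracy is the headline
metric here, matching how this arm is reported.
`top_predictive_words()` back-projects PC coefficients to word space
(`loadings %*% beta`), which reproduces the PC linear predictor exactly
(tested to 1e-10), and ranks the top words toward each group.

## Numerical choices and degenerate inputs

* Strict inequalities everywhere in QC (">" 10%, "<" 0.80, ">" 3 fails).
* Constant profile features z-score to zeros rather than NaN; constant
  predictor columns in the replication arm fail loudly by name.
* `0 log 0 = 0` in entropy; single-class evaluation sets yield NA
  ROC-AUC rather than an error; empty per-language test subsets are
  flagged absent, not fabricated.
* Argmax ties (hyperparameters, mapping selection) resolve to the
  earliest entry.
* All randomness flows through `child_seed(global_seed, label)`, keeping
  every derived seed below 2³¹ and independent of evaluation order.

## Problem sizes used in the shipped tests

The test suite and acceptance script run on reduced problem sizes chosen
to exercise every code path at desk scale: cohorts of 50–1500 subjects,
the full 290-item task for profile construction, 40–100 bootstrap
re-splits (against 1000 in a full analysis), and 50 shuffled-baseline
reruns for null calibration. These sizes are the package's own choices
for fast, deterministic verification; the functions take full-scale
inputs unchanged.

## Known limitations

The Binder scores are English-derived for all languages, as in the
analysis the package models; language-specific re-norming is out of
scope. The synthetic generator's effect magnitudes are deliberately
clear rather than realistic, so classifier scores on synthetic cohorts
exceed anything expected from human data. Medial responses are handled
only through the three coding schemes — no two-dimensional treatment of
three-term systems is attempted. The in-package MLP is a minimal Adam
implementation sufficient for the shipped grids, not a general deep
learning tool.
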