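---
title: "Predicting noninvasive ventilation failure: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting noninvasive ventilation failure: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Noninvasive ventilation (NIV) fails — the patient must be intubated — in
roughly 30% of severe ICU cases, and late recognition of failure carries
high mortality. The clinically useful prediction window is early: before
NIV starts (H0) and after one hour of treatment (H1). Two properties of the
data make this hard for off-the-shelf classifiers. First, failures are a
minority class, which depresses recall exactly where missed diagnoses are
most costly. Second, the predictive signal is substantially *temporal*: the
H0 to H1 trajectory (does oxygenation improve? does respiratory rate come
down?) carries information that a flat feature vector does not expose.

`nivstack` implements a complete pipeline for this problem: a synthetic
cohort generator (the original hospital data are private), a leakage-safe
preprocessing chain, three families of engineered features including an
LSTM-autoencoder representation of the two-point time series, a *modified
SMOTE* oversampler targeting hard minority instances, a three-learner
stacking classifier, the standard metric suite, and additive (SHAP-style)
explanations.

## The synthetic cohort: a stated world

`generate_cohort()` emulates the documented structure of a severe-ICU NIV
cohort rather than any real patient data:

* ~30% failure prevalence (740/2495), 14 diagnosis categories with a long
  tail (AECOPD 45%, pneumonia 26%, ARDS 8%, ...), eight comorbidity flags;
* paired H0/H1 physiological variables drawn from truncated Gaussians with
  reference means and SDs typical of such cohorts (e.g. H0 respiratory rate
  31 +- 7 breaths/min, H0 FiO2 0.42 +- 0.15, H1 PaO2 95 +- 40 mmHg), a
  within-patient H0-H1 latent correlation (default 0.6, exposed as a
  parameter since no empirical value is documented), and physiologic
  clipping bounds;
* the oxygenation index (PaO2/FiO2) computed as the *exact ratio* of the
  generated PaO2 and FiO2 columns, so the arithmetic invariant clinicians
  expect holds in every row. A consequence is that its marginal mean (~171
  mmHg at H0) sits slightly below the reference 178 +- 87, because the
  ratio of two truncated Gaussians is not Gaussian;
* completely-at-random missingness and implausible 6-9 SD spikes, at
  configurable rates, to exercise the cleaning chain.

Outcome labels are drawn first as Bernoulli(failure rate); class signal is
then injected as standardized mean shifts at H1 (failures: RR +0.8, FiO2
+0.7, HR +0.7 SD; GCS -0.7, PaO2 -0.7, pH -0.6 SD; defaults follow the
documented direction of deterioration), attenuated to 40% at H0. Because
the two classes share a covariance structure, the implied posterior
P(failure | features) is exactly a logistic model on the features — so the
"labels-first" construction and a logistic outcome model are the same
stated world, while the configured effect sizes are realized as
class-conditional mean differences *by construction* (verified to +-0.1 SD
at n = 2000 in the tests). Near a clipping bound (GCS, whose mean sits
close to the 15-point ceiling) a configured effect is attenuated; the
effect-recovery guarantees therefore apply to variables away from their
bounds.

What a green test on this cohort does **not** establish: performance on
real EHR data, with informative missingness, measurement artefacts
correlated with severity, more than two time points, or diagnosis-dependent
physiology. The generator is a fixture with the documented statistical
shape, not a simulator.

## Preprocessing

The chain is outlier masking, then median imputation, then z-scoring —
fitted on the training split only and replayed on test data:

* **Outliers**: a value is abnormal when it lies strictly more than 3
  population SDs from the column mean ("3-sigma"); flagged values become
  missing. The multiplier is configurable.
* **Imputation**: per-feature medians of the masked training values.
  Whether the original study computed medians before or after its 80/20
  split is not documented; this package fits on the training split only, the
  leakage-safe reading.
* **Scaling**: `x' = (x - mean)/sd` with the population (divide-by-n) SD —
  one convention had to be chosen; it is documented and covered by tests.
  Zero-variance features are dropped with a warning (the z-score is
  undefined, and they would fail the variance filter anyway).
* **Categoricals**: one-hot encoding; diagnosis categories with fewer than
  20 training occurrences collapse into `Others`, as do categories unseen
  at training time.
* **Split**: `round(0.8 n)` training rows — 1996/499 at n = 2495. An
  optional outcome-stratified split is available but off by default, since
  the documented protocol is a simple random split.

## Feature families

Every column carries a provenance tag (`raw`, `manual`, `expert`, `cross`,
`deep`), so ablations are expressible by tag.

* **Manual temporal** (`temporal_mean_diff`): per paired variable, the mean
  `(H0+H1)/2` and the differential `H1-H0`. The map is invertible, so no
  information is lost or duplicated beyond collinearity.
* **Expert formulas** (`expert_features`): oxygenation index / RR, age x RR,
  RR x HR, RR x HR x FiO2, at both time points (units recorded; a zero RR
  makes the ratio missing, then imputed).
* **Crosses** (`feature_crosses`): pairwise products over the expert
  variable set only — crossing all pairs would explode the dimension with
  noise features.
* **Deep** (`fit_autoencoder` / `encode_features`): an LSTM autoencoder over
  the length-2 sequence of standardized paired measurements. Architecture
  (undocumented in the source work, so fixed here as the smallest credible
  choice): one LSTM cell (input/forget/output gates, tanh candidate) of 32
  hidden units unrolled over H0 and H1; a linear projection of the final
  hidden state to an 8-dimensional latent code; a decoder LSTM fed the code
  at both steps with a linear readout; full-batch Adam (learning rate 0.01,
  30 epochs) on MSE reconstruction loss. The *latent code* — not the
  reconstruction — is appended to the feature set. Training is exactly
  reproducible under a seed; the backward pass is verified against numerical
  differentiation to 1e-6 in the test suite. The autoencoder is fitted on
  the training split only.
* **Selection**: variance filter (default 1e-8) then absolute Pearson
  correlation with the outcome (default 0.01). Defaults are deliberately
  permissive — the filters exist to discard degenerate columns, not to do
  model selection; both thresholds are exposed.

## Modified SMOTE

Classic SMOTE interpolates between a minority point and its k nearest
minority neighbours; it treats easy and hard minority instances alike and
happily synthesizes around isolated noise points. The modified sampler:

1. **Probe**: an RBF-kernel C-SVC (SMO solver, in-package) is fitted on the
   full training partition; minority rows misclassified *in-sample* form the
   hard-instance set. In-sample misclassification is the simplest reading of
   "minority error instances"; no probe protocol is documented.
2. **Isolation removal**: a hard instance is *isolated* iff none of its
   m = 5 nearest neighbours (any class, Euclidean) is minority — the noise
   category of Borderline-SMOTE, whose behaviour this sampler is meant to
   retain. Isolated instances are removed and never seed synthesis.
3. **Clustering**: k-means over the retained hard set; N defaults to the
   square-root rule `max(1, round(sqrt(#retained)))` since no N is
   documented, capped at the number of distinct points.
4. **Synthesis**: `x_new = c_j + u (x_i - c_j)` with `u ~ Uniform(0,1)`,
   cluster j drawn proportional to size, member x_i uniform within the
   cluster, until minority/majority reaches `target_ratio` (default 1).
   The uniform-u and proportional-cluster choices are this package's; only
   the interpolation endpoints are documented.

Every synthetic row records its cluster, centroid, seed instance and u, so
the convex-combination geometry is checkable after the fact (the tests
verify residuals < 1e-9). When the hard set comes back empty — e.g. on
separable data — the sampler falls back to classic SMOTE with a warning
rather than violate its balance contract. Isolation removal happens after
probing, as documented; the reverse order is noted as an alternative but
not implemented.

Baselines behind the same signature: random duplication, classic SMOTE,
Borderline-SMOTE, SVM-SMOTE (support-vector seeding).

## The stacking classifier

Three deliberately heterogeneous base learners — logistic regression
(`stats::glm`), a bagged probability forest, and logistic-loss gradient
boosting with Newton leaf values — produce out-of-fold probabilities under
5-fold stratified cross-validation; those three columns (no raw-feature
passthrough: the documented meta input is the base probabilities alone)
train a logistic meta learner. Base learners are then refit on the full
training data for deployment. Oversampling happens once, before the stack
is fitted, matching the documented stage order.

The forest and GBDT are implemented on a shared compiled CART grower
(variance splitting, per-node feature subsampling) because no suitable
learner packages are available in the target environment; the "categorical-
aware gradient boosting" role is filled by the in-package GBDT over the
one-hot-encoded matrix. The GBDT with default settings (no row subsampling,
all features per node) is deterministic by construction; the forest's
bootstrap is seeded.

## Metrics

Accuracy, precision, recall (`TP/(TP+FN)`), F1 (`2PR/(P+R)`) and ROC AUC in
its Mann-Whitney form (ties count one half). The accuracy denominator is
`TP+FP+TN+FN` — the printed source formula contains an obvious typo ("=`FN`"
for "+FN"); the only reading consistent with "total number of instances" is
used. Zero denominators return 0 with a warning so degenerate folds never
crash a benchmark table. AUC is tested for exact agreement with a
brute-force pairwise oracle, and F1 against the algebraic identity
`2TP/(2TP+FP+FN)`.

## Explanations

* **Tree models**: the polynomial-time path-dependent tree explainer,
  with expectations under each tree's training cover distribution. Verified
  in the tests against brute-force Shapley enumeration on small trees
  (agreement to 1e-9) and additive to 1e-6 on every explained instance.
  Output space is the model margin: class fraction for the forest, log-odds
  for the GBDT — which is why a single-instance prediction can exceed 1 in
  log-odds space while attributions still sum exactly.
* **Logistic regression**: closed form in link space,
  `phi_j = beta_j (x_j - mean(reference_j))`; aliased (NA) coefficients
  attribute zero.
* **The stack**: not a tree, so a seeded permutation-sampling explainer is
  used, with the training split as the reference set. Its telescoping
  construction makes `base + sum(phi) = f(x)` hold exactly for any number
  of permutations; sampling noise affects only the split of credit among
  correlated features (default 20 permutations, 25 background rows).

## Pipeline and reproducibility

`run_pipeline()` chains all stages from one nested config. A single global
seed is fanned out into independent per-stage seeds through a fixed
splitting rule (`sample.int` under the global seed), so stages are
independently reproducible and the whole run is bit-reproducible — the test
suite asserts byte-identical metrics JSON across repeated runs. Stage
toggles (`use_manual`, `use_expert`, `use_cross`, `use_deep`,
`oversample$method`) express the feature-ablation and oversampler-
comparison designs directly.

## Known limitations

* The cohort generator produces continuous GCS values and ignores
  diagnosis-physiology dependence; it is a statistical fixture.
* The SMO solver precomputes the kernel matrix: fine to a few thousand
  training rows, not beyond.
* The permutation explainer's per-feature values (not their sum) carry
  Monte-Carlo noise; rankings from few permutations should be read
  accordingly.
* No hyperparameter search, calibration, multi-class oversampling or
  survival-style censoring: out of scope by design.
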