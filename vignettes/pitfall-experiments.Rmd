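---
title: "Quantifying methodological pitfalls in medical-imaging ML with synthetic experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying methodological pitfalls in medical-imaging ML with synthetic experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlpitfalls)
```

## The problem

Machine-learning models for medical imaging routinely report excellent
internal test-set performance and then fail on external data. Three
mechanisms account for a large share of these failures, and all three are
invisible to internal evaluation:

1. **Violation of the independence assumption** between training and test
   data — duplicated rows from oversampling, near-duplicate rows from
   augmentation, multiple patches per patient scattered across subsets, or
   feature selection fitted on data that includes the future test set.
2. **Misleading performance indicators or baselines** — accuracy under
   heavy class imbalance, or overlap scores (Dice/IoU) interpreted without
   a trivial-baseline comparison.
3. **Batch effects** — class labels confounded with acquisition source, so
   the model learns the source signature instead of the biology.

`mlpitfalls` reproduces each mechanism as a *paired experiment* on
synthetic data: two pipelines identical in every respect except the one
methodological choice under study. Because the generators are fully
specified, each pitfall's inflation is reproducible on a laptop in
seconds, and the *correct* arm's honesty is provable, not just plausible.

## The paired-experiment design

For each repetition, one dataset is generated and handed to both arms:

* the **pitfall arm** applies the transform *before* splitting
  (oversampling, augmentation, feature selection), or splits rows of
  grouped data at random (patient-level pitfall);
* the **correct arm** applies the transform *after* splitting, to training
  rows only — feature indices chosen on the training set are then applied
  to validation and test — or splits group-coherently by patient.

Both arms share the generated data and the classifier seed; only the
ordering or split kind (and the split randomness it entails) differs. The
per-repetition test-set F1 vectors of the two arms are compared with a
two-sided Wilcoxon rank-sum test (default significance level 0.05). A
60/20/20 train/validation/test split is used throughout; the validation
subset is created but deliberately unused — no hyperparameter tuning, so
the acceptance surface stays small. Splits use largest-remainder rounding,
which makes subset sizes exact and deterministic; ties everywhere break
toward the lower index.

The default classifier is 1-nearest-neighbor: a memorizing learner makes
duplicate and near-duplicate leakage maximally visible. Random forest and
logistic regression are available for robustness checks. Features are
standardized with training-set statistics only.

Repetitions whose random split leaves a single class in the training or
test set are flagged and re-drawn with a fresh derived seed (cap 10); with
the default configurations a redraw occurs in well under 10% of
repetitions and at most once in practice.

## What the generators emulate — and what they do not

All feature noise is standard Gaussian; signals are mean shifts along
fixed random unit directions. This is the simplest structure that exhibits
every phenomenon; it does not attempt the heavy-tailed, correlated
structure of real radiomics features.

* `gen_tabular()` — one feature vector per patient with a binary endpoint
  at prevalence `class_fraction` (default 0.1, emulating a rare endpoint
  such as local recurrence). The leakage experiments run it with
  `signal_strength = 0`: under pure noise, *any* apparent skill must come
  from leakage, which turns the pitfall's effect into a testable null
  hypothesis rather than an effect-size claim.
* `gen_patient_patches()` — each patient contributes many rows sharing a
  patient-specific signature (drawn once per patient, per-coordinate
  Gaussian SD `signature_strength`, default 3). This mimics patches that
  share image characteristics irrelevant to the class. With
  `class_signal = 0` a classifier can only recognize *patients*, which is
  exactly what row-level splitting rewards.
* `gen_batch_dataset()` — source A contributes only class-0 samples,
  source B only class-1 (the confound), each with a per-source signature
  offset (SD 3). The external set carries class-0 labels with source B's
  signature, breaking the confound the way deployment data would.
* `gen_ct_volume()` — an ellipsoid phantom: soft-tissue body
  (40 ± 20 HU) in exterior air (−1000 ± 30 HU), two lung ellipsoids, an
  airway tube and bowel-gas pockets of non-lung internal air. Only HU
  contrast and connectivity topology matter for the threshold baseline, so
  no anatomical realism is attempted. The non-lung air fractions (defaults
  8% + 9% of lung volume) are realized to the voxel by construction, which
  pins the ideal thresholder's Dice at 2/(2 + e) ≈ 0.92 — the scale at
  which a "high" overlap score coexists with a qualitatively wrong mask.
  HU noise is clamped at ±4 SD so air lies strictly below −400 HU and
  tissue strictly above it, making the generator exactly self-consistent
  with the −400 threshold.
* `gen_synthetic_slide()` — near-white background with tissue-colored
  blobs from a thresholded smooth random field; the foreground fraction is
  exact to the pixel and separable by the default luminance threshold.
  Real slides have texture, stain variation and luminance overlap that
  this generator does not model, so patch-pipeline tests validate the
  *procedure* (thresholding, rejection rule, caps, determinism), not
  robustness to staining.

Because the generators realize their nominal conditions exactly, a passing
suite demonstrates that the *pipeline machinery* behaves as specified and
that each pitfall produces its inflation under controlled conditions. It
does not certify effect sizes on clinical data: inflation magnitudes
observed on clinical datasets with GPU-scale models depend on the dataset
and the model, and are reproduced here directionally, not numerically.

## Metrics and the Wilcoxon comparison

Accuracy, precision, recall and F1 come from exact confusion counts; F1 is
computed on the positive (minority) class. A zero-denominator metric is
reported `NA` and treated as 0 in aggregates, with a warning — the
conservative reading of a model that never predicts the positive class.

Dice = 2|X∩Y|/(|X|+|Y|) and IoU = |X∩Y|/|X∪Y| treat a pair of empty masks
as perfect agreement (score 1). The identity Dice = 2·IoU/(1+IoU) — hence
Dice ≥ IoU always — is property-tested on random masks and holds exactly,
which is worth remembering whenever a reported Dice looks more
flattering than the corresponding IoU.

The Wilcoxon rank-sum test reports the standardized z of the first
sample's rank sum with tie and continuity correction. For small untied
samples (n₁+n₂ ≤ 30) the p-value comes from the exact rank-sum
distribution via a subset-sum counting recursion; larger or tied samples
use the corrected normal approximation. This mirrors standard scientific
libraries and keeps the small-sample p-values verifiable against
brute-force permutation enumeration (the suite checks every sample-size
split up to n = 10). The normal approximation alone deviates from the
exact permutation p by up to ~0.13 when one sample has fewer than three
values — which is why the exact route exists.

## The baseline segmenter

`baseline_lung_proxy()` composes `threshold_air()` (strictly below
−400 HU; a voxel at exactly −400 is excluded) with `remove_border_air()`,
which removes air components connected to any grid face — the
operationalization of "air outside the body" that needs no anatomical
model. Component connectivity defaults to 6 (face connectivity, standard
for CT air) and may be set to 26. The removal is morphological
reconstruction seeded at the border, iterated to a fixed point; a
breadth-first flood fill serves as its oracle in the tests.

On the default phantom cohort the proxy attains mean Dice ≈ 0.92 while
*every* predicted mask strictly contains non-lung air — a compact
demonstration that a high overlap score is not evidence of an acceptable
segmentation, and that any proposed model must at least beat this trivial
baseline.

## Patch extraction

The whole-slide pipeline downscales by block mean (default factor 4),
thresholds background as mean-channel luminance ≥ 0.8 of full brightness,
then draws uniformly random patch origins on the downscaled image,
rejecting candidates with ≥ 75% background (a candidate at exactly 75% is
rejected) until 200 patches per image are accepted or the attempt budget
runs out. Patches are sampled from the downscaled image, consistent with
the stated downscale → threshold → extract order. Defaults keep the
canonical values (1024-pixel patches); tests and the acceptance script
scale `patch_size` and the image size down, which leaves the counting
behaviour — 110 foreground-rich slides × 200 = 22 000 patches —
unchanged.

## Numerical and design choices

* **Seeds.** One master seed per run; every generator, repetition, arm and
  sub-step derives its own 31-bit stream from it, so multi-part outputs
  are reproducible and regeneratable piecewise. Within a repetition the
  two arms receive identical data and classifier seeds; split and
  transform seeds are arm-specific. That last choice matters: with
  identical split seeds, two *identical* (null) arms would produce
  identical F1 vectors and a degenerate comparison, whereas arm-specific
  split randomness makes null arms exchangeable — the property the
  calibration suite verifies (≤ ~7% rejections at the 5% level over 200
  replications, run with 20 inner repetitions on a 40-patient
  configuration to keep desk-scale runtimes).
* **Feature scoring** is the pooled-variance two-sample t statistic, ties
  broken toward the lower index; a feature with zero pooled variance
  scores 0 when class means agree and infinity when they differ.
* **Oversampling** duplicates minority rows with replacement to exact
  balance — no interpolation (SMOTE-style methods are a different
  mechanism and are deliberately excluded).
* **Problem sizes.** Experiments default to 100 repetitions;
  oversampling/augmentation use 100 patients × 10 features, feature
  selection 100 × 1000 (k = 10), patient-split 20 patients × 50 patches,
  batch 500 per source × 20 features; phantom grids default to 64³. These
  sizes make every experiment reproducible in seconds to a couple of
  minutes on one CPU while leaving each effect unambiguous.
* **Directional stability.** Across replications of each leakage
  experiment, the sign of the mean-F1 gap is stable (≥ 95% of
  replications); for feature selection the *per-repetition* gap is
  noisier — a univariate-filter selection bias is real but modest within a
  single run — which is why the stability property is stated at the level
  of the mean.

## Known limitations

* Gaussian features with mean-shift signals; no correlated or heavy-tailed
  structure, no realistic radiomics feature definitions.
* Lightweight classifiers stand in for the CNN scale of the motivating
  applications; effect sizes are therefore directional analogues.
* Phantoms are ellipsoid-based; the airway/bowel-gas geometry is schematic.
* No DICOM ingestion (NIfTI only for real volumes), no attribution maps,
  no hyperparameter tuning on the validation subset.

## A worked example

```{r example, eval = FALSE}
library(mlpitfalls)

res <- run_paired_experiment(experiment_config("oversampling", seed = 1))
glance(res)
autoplot(res)

bat <- run_batch_effect(experiment_config("batch_effect", seed = 1))
glance(bat)

cohort <- lapply(1:10, function(i) {
  ph <- gen_ct_volume(volume_spec(seed = i))
  list(id = i, volume = ph$volume, lung_truth = ph$lung_truth)
})
evaluate_baseline(cohort)
```
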