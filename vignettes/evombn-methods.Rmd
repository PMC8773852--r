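---
title: "Evolving multi-branch ECG networks: models, operators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving multi-branch ECG networks: models, operators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evombn)
```

## The problem and the model

Myocardial infarction (MI) leaves location-specific traces on a 12-lead ECG:
an inferior infarct shows up on leads II, III and aVF, an anterior one on V3
and V4, and so on. A multi-branch network (MBN) respects this structure by
giving every lead its own 1-D convolutional branch and fusing the twelve
branch outputs in a global head. Two design questions are usually answered by
hand: *how deep* a feature to take from each branch, and *how much* each lead
should count in the fusion. This package answers both automatically:

* **Depth per lead** is encoded as a 12-integer genome
  `L = [l1, ..., l12]`, where `li` is the basic-unit index (a convolution +
  batch normalization + ReLU triple) whose pooled activation becomes lead
  `i`'s feature. Only even indices 2..16 and the top level 17 are admissible:
  adjacent levels carry near-duplicate information, and the top level is the
  conventional MBN choice, so the restriction shrinks the search space
  without losing meaningfully distinct architectures. A genetic algorithm
  (GA) searches this space.
* **Lead weighting** is a lead squeeze-and-excitation (LSE) gate: each lead's
  feature vector is squeezed to a scalar, the 12-vector `u` passes through
  `e = sigmoid(W2 relu(W1 u))`, and lead `i`'s features are rescaled by
  `e_i` before a fully-connected classifier. With `e` forced to 1 the head
  degenerates exactly to the conventional concatenation + fully-connected
  MBN summarizer, which is the ablation baseline used in the tests.

The GA's fitness for a genome is

```
fitness = alpha * F1 + beta * Accuracy - eta * sum(L)
```

with `alpha = 1`, `beta = 0.1`, `eta = 1e-5`: classification performance
dominates (F1 first, accuracy second), and among near-equal performers the
shallowest architecture wins. Both F1 and Accuracy enter on the 0..1 scale;
with a percent-scale accuracy the `beta` term would dominate the F1 term,
inverting the intended priority.

## Preprocessing

Records are downsampled to 250 Hz (`signal::decimate`/`signal::resample`),
denoised per lead, segmented into beats, and z-scored:

* **Wavelet recipe.** `denoise_signal()` performs an 8-level periodized
  Daubechies-6 decomposition, zeroes the level-8 approximation band (below
  roughly 0.5 Hz at 250 Hz — baseline wander) and the level-1 detail band
  (above roughly 62 Hz — high-frequency noise), and reconstructs. The
  wavelet family is fixed; the depth and the choice of suppressed bands are
  this package's realization of "remove noise and baseline wander", and the
  depth is config-exposed (`wavelet_levels`).
* **R-peak detection** runs on denoised lead II, the conventional rhythm
  lead. The built-in detector is the classical derivative → squaring →
  moving-window integration → adaptive-threshold recipe; any detector with
  the `function(x, fs) -> indices` contract can be plugged in.
* **Segmentation** takes 127 samples left and 128 right of each R index
  (inclusive window, 256 samples ≈ one P-QRS-T cycle at 250 Hz). Windows
  crossing a record boundary are dropped rather than padded — padding would
  contaminate the z-score statistics. Indices are 1-based throughout, the R
  convention.
* **Z-score** uses the population standard deviation, `z = (x - mu)/delta`
  per lead; a lead with `delta <= 1e-8` raises an error naming the lead.

## Branch networks

Each branch has exactly 17 convolutional layers: a kernel-7 stem followed by
8 residual blocks of two kernel-3 units. The exact block layout (kernel
sizes, stride placement, widths) is this package's own concrete realization
of a 17-layer 1-D residual stack: temporal stride 2 at units 5, 9 and 13,
where the default width plan (32, 64, 128, 256) also steps up, with a 1x1
projection + BN on the shortcut whenever shape changes. Everything is
overridable through `width_plan`.

Branches are trained **separately per lead** on the full subcategory label
set (feature learning, not final diagnosis), with SGD + momentum 0.9, the
step schedule `lr0 * 10^(-floor(epoch/10))`, and the weighted cross entropy

```
Loss = -sum_i w_i [ y_i log p_i + (1 - y_i) log(1 - p_i) ]
```

with inverse-frequency weights `w_i = N/(c * N_i)`. The loss is implemented
negated relative to a sign-free printed form so that it is nonnegative and
decreases under correct prediction; the per-branch head uses a softmax. Both
forward and backward passes are exact matrix-algebra implementations; the
test suite checks every layer type's gradient against central finite
differences.

Two named profiles set the scale: `"paper"` (widths up to 256, 30 epochs,
batch 128, lr0 0.1) is the full-size recipe; `"desk"` (width 8, 3 epochs,
batch 32, lr0 0.05) is used by the tests and examples. After training, a
`feature_bank` caches the pooled feature of every (lead, level, beat)
triple, so each GA fitness evaluation only trains an LSE head.

## LSE details

* The bank feature `y_i` is already pooled over time; the squeeze `u_i` is
  its mean over channels. This two-stage pooling is required for `u` to be
  12-dimensional, as the gate dimensions `W1 ∈ R^(12/r)×12` demand.
* Excitation is computed **per beat** (input-dependent attention), because
  the gate maps the beat's own squeezed vector, not a learned constant.
* Reduction factor `r = 1` (hidden width 12) by default; `r` must divide 12.
* The gate and classifier layers carry zero-initialized bias terms.
* Head training standardizes each feature dimension over the training beats
  (center/scale stored on the model, re-applied at prediction): frozen-branch
  GAP features are all-positive and badly conditioned otherwise, and the
  30-epoch Adam budget (step size 0.01, batch 32) converges reliably only on
  the standardized scale. These optimizer constants are the package's
  defaults for its desk-scale study sizes.
* Binary heads use a single sigmoid output with per-sample class weights;
  multiclass heads use a softmax. In the symmetric two-term binary form of
  the weighted cross entropy the two class weights collapse into one factor,
  so weighting is applied per sample by true class instead.

## GA operators

* **Initialization:** 100 genomes, each element uniform over the 9 admissible
  levels.
* **Selection:** sort by fitness, keep the top 10 as parents (elitism). Ties
  break toward the smaller level sum (lighter model), then insertion order.
* **Crossover:** one-point splice after position 6 — exactly the boundary
  between limb and precordial leads, so a child inherits one parent's
  complete limb plan and the other's complete precordial plan.
* **Mutation:** pick `k = 3` distinct positions, reset each to 2 with
  probability 0.8 or 17 with probability 0.2. A reset that lands on the
  current value still counts as mutated. The operator is applied to each
  offspring independently with probability `pm = 0.25` — and to offspring
  only: mutating the retained elites would break the monotone maximum
  fitness that elitist selection implies.
* **Offspring policy:** `pop_size - n_parents = 90` offspring per generation
  from uniformly drawn distinct parent pairs (one surplus child discarded
  when the count is odd); parents + offspring form the next generation.
* **Stopping:** at most 10 generations, stopping once the maximum fitness is
  unchanged (within 1e-12) for 2 consecutive generations.
* **Fitness evaluation:** the bank-backed evaluator carves a patient-wise
  80/20 fit/validation split from the training fold, trains an LSE head on
  the 80%, and scores F1 (macro-averaged for multiclass, positive-class for
  binary) and accuracy on the held-out 20%. Every genome derives its own RNG
  substream from the run seed, so fitness is a deterministic function of
  (genome, seed) — which also makes the evaluation cache sound: a genome
  seen before costs no new training run.

## Diagnosis tasks and evaluation

Detection collapses all MI subcategories to one positive class. Localization
runs either one multiclass head or a group of one-vs-rest binary heads — one
GA run and one genome per class, so each genome can specialize on its
territory's leads — with the prediction being the class of maximum positive
probability (ties broken by the fixed order HC, AMI, ASMI, ALMI, IMI, ILMI).
OMI has no fixed territory: it participates in branch training but is
excluded from localization.

Metrics follow the standard one-vs-rest definitions; F1 is computed as
`2TP/(2TP + FP + FN)` (equivalently the harmonic mean of sensitivity and
precision) — a printed variant with TN in the denominator is treated as a
typographical slip, since it contradicts the harmonic-mean identity printed
alongside it. Sensitivity is undefined for a class without positive samples;
such classes are reported as `NA` and excluded from mean rows with a warning.

Cross-validation is **inter-patient**: folds partition patients, never
beats, stratified by class, and the structural guarantee (no patient on both
sides) is asserted on every split. Architecture transfer freezes the branch
weights and the genomes and retrains only the LSE heads on the target data.

## The synthetic generator

`generate_record()` and `generate_beat_dataset()` emulate exactly the
properties the pipeline depends on: P/QRS/T morphology (Gaussian P and T
bumps, a narrow biphasic QRS), distinguishable per-lead gains, planted
R-peak ground truth, baseline wander and white noise, and — crucially —
class signal confined to each MI class's anatomical leads (anterior V3/V4,
septal V1/V2, lateral I/aVL/V5/V6, inferior II/III/aVF). The default
perturbation is an ST-segment elevation of 0.3 x the lead's QRS amplitude,
strong enough for attention-recovery experiments at small sample sizes;
Q-deepening and T-inversion variants are available. OMI, a catch-all class,
perturbs a random 2-lead subset at half magnitude. Patients carry exactly
one class each, which makes inter-patient splitting well defined.

What the generator does **not** emulate: heart-rate variability and
arrhythmia, inter-patient morphology variation beyond noise, electrode
artifacts, and the class-imbalance structure of clinical databases. Passing
tests on this data demonstrate that the machinery is correct and that the
search recovers planted structure — not clinical-grade performance.

## Problem sizes and numerical choices

The test suite and examples run at deliberately small scale, chosen as the
smallest sizes at which every property under test is stable: width-8
branches, 1-3 training epochs, 40-250 beats, GA populations of 10-30 for
pipeline runs (the operator-level tests use the full defaults: population
100, 10 parents, 10 generations). Probabilities are clipped at `1e-7` inside
the cross entropy; batch normalization uses eps `1e-5` and momentum 0.1;
fitness stagnation uses tolerance `1e-12`; z-scoring declares a lead
degenerate below sd `1e-8`. The periodized wavelet transform requires the
padded length to be a multiple of `2^levels`; the reflection padding is
trimmed away after reconstruction.

## Known limitations

* No GPU or compiled backend: the networks are plain R matrix algebra, sized
  for desk-scale studies, not for full clinical databases.
* WFDB binary files are not read directly; records enter as CSV matrices or
  through the synthetic generator.
* The 17-layer block layout is one concrete realization of the depth
  constraint; published figure-level details beyond the layer count are not
  reproduced.
* Beat-level (not record-level) diagnosis: no aggregation of beat
  predictions into a per-record verdict.
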