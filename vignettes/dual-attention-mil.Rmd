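---
title: "Dual-attention adaptive bag embeddings for weakly-labelled volumes: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-attention adaptive bag embeddings for weakly-labelled volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(attnmil)
```

## The model and its assumptions

The package targets cohorts where outcomes exist only at the patient
level. Each patient's 3D volume is a *bag*; slice-level positions are
*instances*; the bag label obeys the multiple-instance constraint (a bag
is negative iff all of its instances are). The working assumptions are:

* the predictive signal of a positive patient is concentrated in a small
  number of key slices, while most slices are background;
* a shared convolutional feature extractor can represent both background
  and key-slice appearance;
* patient-level supervision plus an attention bottleneck is enough to make
  instance scores land on the key slices, without any slice labels.

The computation chains six pieces. Min-max normalization maps a volume to
`[0, 1]` (the formula's printed range; a `symmetric = TRUE` flag rescales
to `[-1, 1]` for users who prefer the signed convention — the two
conventions appear interchangeably in the literature and we do not guess
an intent, we expose both with the printed one as default). A compact 3D
conv stack produces one instance vector per depth position of its final
feature map. The first attention layer scores instances
(`a = softmax(w' tanh(V h'))`) and pools them. The top-M instances by `a`
become the critical set, with M adapted by a small sigmoid controller.
The second layer projects instances to queries/values and calibrates each
instance by its inner-product softmax distance to the critical set; the
bag embedding is the distance-weighted sum of values. A linear sigmoid
head on the pooled vector and the bag embedding yields the bag score for
stage-1 training with binary cross-entropy; the flattened embedding is the
patient's deep-feature block for the downstream fusion model.

## Parameters that matter

* `cohort_config()` — the synthetic study conditions. Defaults: 120
  patients, prevalence 0.4, volumes 32×32×16 voxels, 1–2 key slices per
  positive patient, lesion amplitude 50 intensity units on voxel noise of
  SD 10 (a conspicuous but local bright lesion, 5× noise), 758
  radiomics-style columns of which 15 carry a 0.8-SD class shift, and
  dosimetric columns whose means/SDs/shifts mirror the published pattern
  of lung V5–V30 and mean lung dose in a screened radiotherapy cohort
  (shifts of roughly 0.2 SD — deliberately weak, as in real tables).
* `backbone_config()` — widths (8, 16, 32), 3×3 in-plane kernels with
  depth extent 3 in the first block and 1 afterwards, max pooling with
  spatial factors (2, 2, 2) and depth factors (2, 2, 1), instance
  dimension `d = 32`. For 16-slice volumes this yields k = 4 instances
  whose provenance intervals are 4 consecutive slices each.
* `stage1_config()` — Adam, learning rate 1e-4, weight decay 1e-5, batch
  4, at most 100 epochs, early stopping with patience 15 on validation
  loss. These defaults suit fine-tuning from a good initialization; the
  desk-scale benchmark configs (`run_ablation()`, `run_config()`) use
  learning rate 1e-3, 25 epochs, patience 8, which is what a
  randomly-initialized compact network needs to converge on the synthetic
  task sizes used here.
* `mlp_config()` — one hidden layer of 32 sigmoid units (`hidden = 0`
  degrades gracefully to a single sigmoid neuron), threshold 0.5, inputs
  re-standardized with training-fold statistics so the three fused blocks
  arrive on one scale (disable with `standardize = FALSE`).
* Screening and selection — pooled-variance t-test by default (`var_equal
  = FALSE` for Welch), chi-square without continuity correction (`correct
  = TRUE` to enable), strict `p < alpha` with an `inclusive` flag for
  `p <= alpha`; LASSO penalty grid of 100 log-spaced values from the
  smallest all-zero penalty down to 1e-4 of it, always containing 0.002,
  with 5-fold CV-MSE selection and ties broken toward the sparser model.

## What the generator emulates — and what it does not

Positive patients receive 1–2 bright ellipsoid patches, each confined to
one slice, at random in-plane positions: a spatially localized,
slice-attributable signal matching the slice-as-instance premise. Every
volume also contains constant dark and bright anchor structures (the
synthetic analog of air and dense tissue, which pin the intensity range of
any real scan). These anchors matter: they make the per-volume min-max
mapping identical across patients, so the class signal cannot leak into
every instance through the normalization denominator and the only way to
discriminate bags is to find the key slices. Without them an
instance-attention model has no pressure to localize — a useful reminder
of how easily weak supervision latches onto global intensity statistics.

The clinical table reproduces the screening outcome pattern of a typical
univariate table: six categorical features built as randomization-balanced
nulls (the target marginal is allocated proportionally within each class
and permuted, so their class association is zero by construction, not
merely in expectation) and five continuous dosimetric features with small
positive mean shifts. The radiomics table is Gaussian with additive class
shifts in a known sparse support, making LASSO recovery directly checkable.

The generator does **not** emulate DICOM metadata, Hounsfield-unit
textures, inter-slice anatomy, dose-distribution maps, scanner effects, or
correlated radiomics features. Passing tests on this cohort therefore
demonstrate that the machinery is implemented correctly and that attention
can localize planted signal under the MIL premise — not that the model
generalizes to clinical CT.

## Numerical choices

* Softmaxes subtract their maximum before exponentiation.
* Top-M selection ranks by descending score with ascending-index
  tie-break; it is a hard, stop-gradient operation, so gradients reach the
  first attention layer through the pooled vector and the second layer
  through the distance weights only. The stage-1 head therefore reads
  both the pooled vector and the bag embedding — the minimal head that
  gives both attention layers a gradient path.
* The distance-weight normalizer follows the printed `1/N` form (weights
  sum to `M/k`); the `1/M` average (weights sum to 1) is selectable. Both
  are asserted exactly (1e-9) in the tests.
* The adaptive M is updated once per bag per training forward pass from
  the current top scores, starts at `ceil(k/2)`, rounds half-up, clamps to
  `[1, k]`, and is frozen at its running median for inference so that
  inference is deterministic. The controller input is the top-score
  softmax padded/truncated to length 8 (renormalized after truncation).
  No gradient survives the rounding, so the controller keeps its
  initialization — it is a confidence-driven schedule, not a learned
  layer; making it learnable would require a relaxation the formulation
  does not define.
* LASSO is cyclic coordinate descent on the `(1/2M)·RSS + λ‖β‖₁`
  objective with an unpenalized intercept, convergence when the largest
  coefficient change in a sweep falls below 1e-7, at most 1e5 sweeps,
  active-set iterations between full sweeps, and Gram-matrix residual
  bookkeeping when p ≤ n (small strongly-correlated designs need many
  sweeps; the Gram path makes them cheap). glmnet agrees to ~1e-8 on the
  same objective and serves as the independent oracle in the tests, never
  as the implementation.
* Degenerate inputs fail loudly: constant volumes cannot be normalized,
  empty bags have no label, empty critical sets are rejected, zero-variance
  columns are dropped from standardization with a warning, single-class
  outcomes abort model fits, and an AUC on single-class truth is returned
  as NA with a warning while the thresholded metrics are still computed.
* All randomness flows from one integer seed through named streams
  (`stream_seed`), so adding a component never perturbs another's draws
  and every artifact — cohort, training, folds, bootstrap — reproduces
  bit-identically.

## Open design points, resolved

* *Instance granularity.* The formulation is ambiguous between
  slices-as-instances and per-position features. The default treats each
  depth position of the final feature map as one instance (preserving 3D
  context), with a `per_slice_window` alternative. Kernel depth is 3 only
  in the first block so an instance's receptive field stays close to its
  own slice interval; with full-depth kernels everywhere, every instance
  sees most of the volume and slice attribution becomes meaningless.
* *Stage-1 supervision.* The stage-1 head and loss are not specified by
  the formulation; a linear sigmoid head with binary cross-entropy is the
  minimal choice consistent with the downstream sigmoid predictor.
* *Heads.* One query/value pair by default (as printed); with several
  heads the distance weights are averaged before the embedding.
* *LASSO response.* The selection objective is squared error on the
  binary outcome, as printed; a logistic variant is deliberately out of
  scope.
* *Cross-validation protocol.* The evaluation reports each validation
  fold and, separately, an untouched test set; feature selection uses
  training patients only.

## Problem sizes

The recovery benchmark uses 120 patients with 32×32×16 volumes, the tiny
backbone above, and seeds 1–3 (about two minutes per seed on one CPU).
The screening-chain test uses 3000 patients with minimal volumes, sized by
power arithmetic so that ~0.2-SD dosimetric shifts are detected with
near-certainty at α = 0.05. The invariant and oracle suites run on bags
of k ≤ 10, d ≤ 8 in well under two minutes.

## Known limitations

* The backbone is a compact stand-in with the same contract as a large
  3D CNN (headless feature extraction, per-depth-position instances); a
  pretrained-weight loading hook exists but no pretrained weights ship.
* At desk scale the planted lesion must be strong enough to learn from
  120 patients, which pushes every deep and fused variant to ceiling
  AUCs on the 24-patient test set; ordering comparisons between saturated
  variants are then decided by one or two patients. The discriminating
  observable on this benchmark is instance-level localization, which the
  acceptance script reports per seed.
* Radiomics feature *extraction* from images is an external adapter by
  design (`extract_radiomics()` is a declared hook); the package fixes
  only the feature-space schema and naming.
* The bootstrap AUC interval is a percentile interval; analytic (DeLong)
  intervals and calibration analyses are out of scope.
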