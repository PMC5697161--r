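---
title: "Cost-sensitive diagnosis of imbalanced ocular images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-sensitive diagnosis of imbalanced ocular images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(csresnet)
```

## The problem

Retro-illumination photographs of the eye show the crystalline lens as a
bright, near-circular disc; opacities of the posterior capsule (PCO) appear
as darker lesions inside it. Severe cases need Nd:YAG laser surgery but are
a minority of clinical images — a typical cohort holds 735 positive against
1970 negative samples, an imbalance of roughly 2.7:1. A classifier trained
to maximize plain accuracy on such data buys specificity with sensitivity:
it misses exactly the patients that matter. The false negative rate (FNR =
1 − sensitivity) is therefore the quantity this package is organized
around.

Two remedies are implemented side by side. *Data-level* methods rebalance
the training sample (SMOTE, borderline-SMOTE, random under-sampling).
*Algorithm-level* cost sensitivity leaves the data alone and reweights the
loss so that missing a minority sample costs `C_min ≥ 1` times more than
missing a majority sample (correct decisions cost zero). A third option,
threshold moving, reweights only the predicted posteriors at test time.

## The cost-sensitive loss

For a mini-batch `{(x⁽¹⁾,y⁽¹⁾),…,(x⁽ᵐ⁾,y⁽ᵐ⁾)}` with `k` classes and
weights `w` (one row per class, bias absorbed as a constant feature):

$$J(w) = -\frac{1}{m}\sum_{i=1}^m \sum_{j=1}^k I\{y^{(i)}=j\}\,
C\{y^{(i)}=\text{min\_class}\}\,
\log \frac{e^{w_j^\top x^{(i)}}}{\sum_s e^{w_s^\top x^{(i)}}}
+ \frac{\lambda}{2}\sum w^2$$

with gradient, for every class row `j`,

$$\nabla_{w_j} J = -\frac{1}{m}\sum_{i=1}^m
C\{y^{(i)}=\text{min\_class}\}\; x^{(i)}
\left(I\{y^{(i)}=j\} - p(y^{(i)}{=}j \mid x^{(i)}; w)\right) + \lambda w_j.$$

The cost factor multiplies only the true-class log term; the softmax
normalizer is unweighted. The gradient above is the exact derivative of
that reading, and the test suite verifies the pair against central
differences to below 1e-6 relative error on random small instances. With
`C_min = 1` both reduce exactly to ordinary softmax regression with weight
decay — same code path, so the cost-free baseline is a true degenerate
case, not a parallel implementation.

Optimization is plain mini-batch gradient descent (no momentum): batch size
64, initial rate 0.001, 2000 iterations, rate divided by ten every 500
iterations, with loss/accuracy logged every 50. These are the
`train_config()` defaults. Batches are drawn by epoch-wise seeded shuffling
without replacement. `λ` defaults to 1e-4 and the bias column is excluded
from the decay term; both choices are conventional and configurable.

## Localization

`localize_lens()` applies Canny edge detection and a Hough circle transform
twice: a coarse pass on the full image, then a crop around the detected
circle and a refining pass inside it. Design choices the procedure itself
does not fix:

- Canny thresholds are *quantiles* (0.7 / 0.9) of the non-zero gradient
  magnitude rather than absolute values, so detection survives exposure
  changes; Gaussian pre-smoothing uses sd 2 px.
- Hough radii span [0.15, 0.45] of the shorter image side (step 2 px
  coarse, 1 px fine). Votes use per-radius deduplicated circle offsets, so
  a peak's score approximates the number of supporting edge pixels.
  Ranking ties break toward the larger radius, then the smaller (cy, cx) —
  determinism matters more than the tie itself.
- Crops are padded by 15% of the radius, clipped at frame borders with
  edge replication, and resized bilinearly to 128 x 128 (bilinear because
  it is smooth and label-preserving; severity is defined by *relative*
  lesion geometry, which scaling leaves unchanged).
- Failure (no Hough peak above a minimal support of 8 edge pixels) raises
  a classed condition carrying the pass index; evaluation counts failures
  as IoU 0.

Accuracy is scored as the IoU of the detected circle's bounding square
against the ground-truth circle's bounding square, averaged over samples.
On 100 synthetic images the pipeline reaches mean IoU ≈ 0.96 (the
acceptance script recomputes this).

## Network building blocks

Batch normalization standardizes each channel by the mini-batch mean and
biased variance, then applies the learned affine `y = γx̂ + β`
(`ε = 1e-5`, running-average momentum 0.9, `γ = 1`, `β = 0` at
initialization). The bottleneck residual block is conv1x1 → BN → ReLU →
conv3x3 → BN → ReLU → conv1x1 → BN, added to an identity shortcut (or a
projection conv + BN when width or stride changes) and passed through a
final ReLU. The reference constructor assembles the full-depth layout — 7x7
stem with 64 kernels, max pool, stages repeated (3, 4, 6, 3) with widths
64–256 / 128–512 / 256–1024 / 512–2048 — totalling 16 residual blocks and
48 in-block convolutions. The stage pattern (3, 4, 6, 3) with projection
shortcuts is the unique standard bottleneck layout consistent with those
totals.

All layers carry hand-written backward passes, checked against
central-difference gradients on toy tensors (relative error below 1e-4).
Training end to end is only sensible for `build_mini_arch()` (4 blocks, 12
convolutions, 32 x 32 inputs) — the full 50-layer network is exercised
shape-only, since training it meaningfully requires accelerators and
transfer learning, which are out of scope. Augmentation implements the two
stated transforms: horizontal reflection (probability 0.5) and integer
translation within ±`max_shift` pixels with edge replication; other
transforms may reasonably hide behind the phrase "image transformation",
and the knob is exposed.

## Synthetic data: what it emulates and what it does not

`generate_eye_image()` renders a bright pupil disc (intensity 0.85) on a
darker background (0.2), optionally with a *soft* iris annulus and speckle
blobs outside the pupil — structured distractors with deliberately smooth
radial profiles, so they perturb edge detection without forming a second
clean circle — plus dark circular lesions inside the pupil and Gaussian
pixel noise (sd 0.02). The label is 1 when lesions cover more than 10% of
the pupil area. Real severity grading is done by ophthalmologists from
opacity location, area and density; the area threshold is an invented,
configurable surrogate, and lesion morphology parameters are free knobs
because no quantitative description of real lesions is available. Passing
tests on this generator therefore demonstrate that the *pipeline* is
correct and that its comparative claims hold under a controlled imaging
model — not that the specific accuracy numbers transfer to clinical
images. One global seed fans out to per-image substreams, so image `i`
never depends on how many images follow it.

`generate_feature_dataset()` provides the fast tabular substrate: two
spherical unit-variance Gaussians separated by `class_separation` along the
first axis. For the imbalance experiments the conditions are fixed once:
class sizes 147 : 394 (one cross-validation training share of 735 : 1970),
separation 2, and a probe learning rate of 0.05. Separation 2 was chosen
because the converged cost-free baseline then reproduces the reference
operating point — accuracy ≈ 0.86, sensitivity ≈ 0.70, specificity ≈ 0.93,
i.e. a majority-biased classifier — which is the regime the cost-sensitive
method exists to correct. The probe rate 0.05 (not the deep-net default
0.001) lets two-dimensional softmax regression actually converge within
the same 2000-step budget; it is a probe-scaling choice, not a tuning knob.

## What the cost factor can and cannot buy here

On these Gaussians the effect of `C_min` is analytically transparent: a
converged probabilistic linear classifier thresholds the log-odds at
`−log(C_min · n_min/n_maj)`, so `C_min` shifts the operating point along a
fixed ROC curve. Sensitivity is monotone non-decreasing and specificity
non-increasing in `C_min` (a property test checks both), and the G-mean is
maximized when the cost exactly cancels the imbalance,
`C_min ≈ n_maj/n_min ≈ 2.7`. A cost of 12 — appropriate on the clinical
feature space it was selected for — overshoots that optimum on
unit-covariance Gaussians: at separation 2 the 10-seed median G-mean is
≈ 0.82 at `C_min = 1`, ≈ 0.85 at `C_min = 4`, and ≈ 0.76 at `C_min = 12`,
while sensitivity rises 0.72 → 0.96. This is a structural property of the
synthetic family (symmetric classes make G-mean symmetric in the log-odds
offset), not an implementation artifact, and the package reports it as
measured.

## Experimental protocol

- `stratified_kfold()` deals each class round-robin after a seeded
  shuffle, so per-fold positive counts differ by at most one (735
  positives split 147 per fold at k = 5).
- `grid_search_cost()` trains one classifier per cost value on a single
  fixed four-fifths/one-fifth stratified split (per-point cross-validation
  is available but costly and was not the original procedure) and records
  accuracy and FNR. The selected cost is the smallest value in the widest
  contiguous region with accuracy ≥ 0.9 and FNR ≤ 0.14 — a formalization
  of reading stability off the two reference lines; when no point
  qualifies (common at desk scale) the G-mean maximizer is returned.
- `run_comparison()` gives every method identical fold memberships, so
  differences are paired; per-fold metric reports are aggregated as mean
  and sample (n−1) standard deviation, and pooled ROC/PR curves are kept
  per method.
- Undefined 0/0 metrics propagate as `NA` and are dropped from fold
  aggregation — silently reporting 0 would corrupt fold means.
- AUC is the trapezoid over the threshold sweep at unique score values;
  tied scores collapse into one operating point, which makes the trapezoid
  equal the Mann–Whitney pair statistic with half-credit for ties
  (property-tested exactly).

## Numerical choices and degenerate inputs

Softmax probabilities are computed with row-max subtraction; BN adds
`ε = 1e-5` inside the square root; a constant image yields an all-zero
edge map (not an error) while an empty edge map yields an empty candidate
list; GLCM correlation on a single-valued image is defined as 0; LBP with
`P = 9` is honoured literally (512-bin histogram) with radius 1 by default,
`P = 8` giving the textbook variant; Haar features use the orthonormal
convention so subband energies sum to the pixel energy; resampling ratios
round toward the minority count. Problem sizes in tests and the acceptance
script (images of 256 px, 100-image localization runs, 2000-iteration
probes, 10-seed medians) were sized for a single-CPU workstation.

## Known limitations

- The full-depth network is constructed and shape-checked but not trained;
  transfer learning from pretrained weights is deliberately out of scope.
- The synthetic imaging model has no Purkinje reflections, no color, and
  simplistic lesion morphology; clinical performance claims cannot be read
  off it.
- SIFT appears among the conventional baselines in the source material but
  is a pre-existing descriptor; it is not reimplemented here.
- Borderline-SMOTE implements variant 1 (interpolation among minority
  neighbours) with Euclidean distance on standardized features; the
  originating description fixes neither.
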