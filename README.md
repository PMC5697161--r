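# csresnet

Cost-sensitive residual networks for imbalanced ocular image diagnosis.

Severe posterior capsular opacification (PCO) after pediatric cataract
surgery needs Nd:YAG laser treatment, but severe cases are a small minority
of the retro-illumination images captured in the clinic (a typical cohort:
735 positive vs 1970 negative). A classifier trained on such data drifts
toward the majority class and misses the patients who most need care. This
package implements, at desk scale and fully testable without clinical data,
the complete diagnosis framework for this problem:

- **Lens localization** — the crystalline lens appears as a bright,
  near-circular disc; it is found by twice-applied Canny edge detection and
  Hough circle transformation (coarse detect, crop, refine), cropped and
  resized to 128 x 128, and scored by bounding-box intersection-over-union
  `IoU = area(B_p ∩ B_gt) / area(B_p ∪ B_gt)`.
- **Cost-sensitive softmax cross-entropy** — the core method. For a
  mini-batch of `m` samples with labels `y(i)` over `k` classes,

  ```
  J(w) = -(1/m) Σᵢ Σⱼ I{y(i)=j} · C{y(i)=min_class} · log pⱼ(x(i))
         + (λ/2) Σ w²
  ```

  where `C = C_min ≥ 1` for minority (severe) samples and 1 otherwise, with
  analytic gradient

  ```
  ∇_wⱼ J = -(1/m) Σᵢ C{y(i)=min_class} · x(i) · (I{y(i)=j} − pⱼ(x(i))) + λ wⱼ
  ```

  minimized by mini-batch gradient descent (batch 64, initial learning rate
  0.001 reduced tenfold every 500 of 2000 iterations).
- **Residual network building blocks** — batch normalization + scaling
  (`y = γ·(x−μ_m)/√(σ²_m+ε) + β`), bottleneck residual blocks
  (1x1 → 3x3 → 1x1 convolutions with identity/projection shortcuts), the
  reference 50-layer constructor (16 blocks, 48 in-block convolutions, 7x7
  stem with 64 kernels) and a trainable desk-scale mini variant, all with
  forward *and* backward passes in plain R, verified against
  central-difference gradients.
- **Comparison baselines** — SMOTE, borderline-SMOTE and random
  under-sampling (k = 5, target ratio r = 1); LBP (P = 9), two-level Haar
  wavelet, and co-occurrence texture features; random-forest (300 trees)
  and linear-SVM adapters.
- **Imbalance-aware evaluation** — sensitivity, specificity, precision, F1,
  G-mean = √(SEN·SPC), ROC/PR curves with trapezoidal AUC, stratified
  fivefold cross-validation, and the cost-factor grid search with
  accuracy/FNR curves.
- **Synthetic data** — a retro-illumination image generator (bright pupil
  disc, iris/sclera distractors, opacity lesions driving the severity
  label) with known circle ground truth, plus Gaussian feature datasets,
  so every claim above is testable.

## Worked example

```r
library(csresnet)

# A synthetic retro-illumination image with lesions, and its localization
eye <- generate_eye_image(eye_image_params(lesion_count = 4,
                                           lesion_radius_range = c(12, 20)),
                          seed = 7)
loc <- localize_lens(eye$image)
cat(sprintf("label %d | true circle (%.0f, %.0f, r=%.1f) | detected (%.0f, %.0f, r=%.0f) | IoU %.3f\n",
            eye$label, eye$circle$cx, eye$circle$cy, eye$circle$r,
            loc$circle$cx, loc$circle$cy, loc$circle$r,
            iou(circle_bbox(loc$circle), circle_bbox(eye$circle))))

# Cost-free vs cost-sensitive training on imbalanced Gaussian features
train <- generate_feature_dataset(147, 394, dim = 2, class_separation = 2,
                                  seed = 11)
test  <- generate_feature_dataset(147, 394, dim = 2, class_separation = 2,
                                  seed = 1011)
cfg <- train_config(lr0 = 0.05, seed = 11)
for (cm in c(1, 12)) {
  fit <- train_cs_softmax(train, cost_spec(c_min = cm), cfg)
  rep <- metric_report(test$label, predict(fit, test, "class"),
                       predict(fit, test, "prob")$p1)
  cat(sprintf("c_min = %2d : ACC %.3f  SEN %.3f  SPC %.3f  G-mean %.3f  AUC %.3f\n",
              cm, rep$accuracy, rep$sensitivity, rep$specificity,
              rep$g_mean, rep$auc_roc))
}
```

prints

```
label 1 | true circle (128, 128, r=71.7) | detected (128, 128, r=72) | IoU 0.991
c_min =  1 : ACC 0.884  SEN 0.735  SPC 0.939  G-mean 0.831  AUC 0.923
c_min = 12 : ACC 0.699  SEN 0.946  SPC 0.607  G-mean 0.757  AUC 0.924
```

The localizer recovers the lens circle to within a pixel (IoU 0.991). The
cost factor moves the operating point: at `c_min = 12` the minority
sensitivity jumps from 0.735 to 0.946 — the fraction of severe cases missed
(FNR) falls from 26% to 5% — at the price of specificity; the ranking
quality (AUC) is unchanged, as cost weighting shifts the decision boundary
rather than the learned representation. `grid_search_cost()` maps this
trade-off over a whole cost grid and picks a stable operating region, and
`run_comparison()` scores competing methods (plain, cost-sensitive,
SMOTE/borderline-SMOTE/under-sampling rebalancing, random-forest baselines)
under shared stratified folds.

A command-line front end over the same functions ships in
`inst/scripts/csresnet-cli.R` (subcommands `simulate`, `localize`,
`extract`, `rebalance`, `train`, `grid-search`, `compare`).

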