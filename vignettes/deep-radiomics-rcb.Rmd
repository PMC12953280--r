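---
title: "Deep radiomics from segmentation bottlenecks: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep radiomics from segmentation bottlenecks: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(deepRCB)
```

## The problem

After neoadjuvant chemotherapy (NAC) for breast cancer, the residual cancer
burden (RCB) quantifies how much invasive disease remains at surgery. It is
a continuous pathology index,

$$\mathrm{RCB} = 1.4\,(f_{inv}\, d_{prim})^{0.17} +
  \left[4\,(1 - 0.75^{LN})\, d_{met}\right]^{0.17},$$

computed from the invasive cellularity of the tumor bed ($f_{inv}$), the
tumor-bed diameter term ($d_{prim}$, mm), the number of positive lymph
nodes ($LN$) and the largest nodal metastasis ($d_{met}$, mm), and is
divided into four classes: RCB-0 (score exactly 0, pathological complete
response, pCR), RCB-I $(0, 1.36]$, RCB-II $(1.36, 3.28]$ and RCB-III
$(> 3.28)$; scores on a boundary go to the lower class. RCB-0/I patients
are *responders*. `rcb_index()` and `classify_rcb()` implement exactly this
definition, and every synthetic outcome in the package is produced through
it, so the invariants (pCR $\Leftrightarrow$ score $0$ $\Leftrightarrow$
empty post-treatment mask) hold by construction rather than by bookkeeping.

The package asks whether the *internal representation* of a tumor
segmentation network predicts RCB from dynamic contrast-enhanced MRI
(DCE-MRI) taken before and after NAC — and whether it adds anything over
two clinical-radiological baselines: post-treatment tumor volume (plus the
volume change from baseline), and volume plus receptor subtype
(TN, ER+/HER2−, HER2+).

## Pipeline overview

1. **Preprocess** (`crop_breast_region`, `register_series`,
   `resample_to_spacing`, `carry_forward`, `median_spacing`): crop in the
   anterior-posterior direction between 10 mm anterior of the nipple and
   50 mm posterior of the intermammary cleft; register every post-contrast
   volume to the pre-contrast volume; resample the cohort to the
   training-set componentwise-median voxel spacing; pad the dynamic series
   to five post-contrast volumes by carrying the last acquired series
   forward.
2. **Segment** (`region_grow`, `seg_model`, `seg_train`, `seg_predict`,
   `dice`): semi-automatic ground truth by seeded constrained region
   growing; three small encoder–decoder networks that expose their
   bottleneck.
3. **Extract** (`downsample_mask`, `extract_features`, `delta_features`,
   `build_feature_sets`): per examination, aggregate the bottleneck
   activations over the coarse voxels overlapping the tumor mask; form
   pre, post and delta ($\mathrm{pre} - \mathrm{post}$) feature sets.
4. **Model** (`variance_filter`, `fit_reduction`, `fit_rf_cv`,
   `clinical_model`, `fit_ensemble`): per network, variance filter
   $\rightarrow$ per-set PCA $\rightarrow$ random forest regression of the
   RCB score with 5-fold cross-validated hyperparameter selection; the two
   clinical baselines use their 2 or 5 features directly (no PCA, no
   filter); a stacking ensemble combines the three network models and the
   volume+subtype model by nonnegative least squares with zero intercept.
5. **Evaluate** (`spearman_eval`, `roc_auc`, `delong`, `cv_auc_ci`,
   `pc_association`, `cohort_compare`, `evaluation_report`): Spearman
   correlation of predicted versus actual RCB; AUC for pCR vs non-pCR and
   responder (RCB-0/I) vs non-responder (RCB-II/III) with DeLong confidence
   intervals and paired tests against a reference model; influence-function
   confidence intervals for cross-validated AUC.

`run_pipeline()` ties the stages together with derived per-stage seeds and
a checksummed manifest; a rerun with an identical configuration is
bit-identical.

## The segmentation networks

No R deep-learning framework is assumed: the three architectures are
implemented in the package itself (Rcpp convolution kernels, hand-written
backward passes, Adam optimizer, positive-weighted cross-entropy plus soft
Dice loss), at desk scale with configurable widths:

* `unet3d` — a two-level 3D U-Net with skip connections; bottleneck
  downsample $4 \times 4 \times 4$.
* `attn-unet2d` — a 2D U-Net with an additive attention gate on the skip
  connection, applied slice-wise (implemented as 3D operations with unit
  extent along $z$, which is mathematically identical); in-plane
  downsample 4 (or 2, below), $z$ at full resolution.
* `vqed2d` — a 2D vector-quantized encoder–decoder: the bottleneck is
  snapped to the nearest entry of a learned codebook (straight-through
  estimator, commitment term $\beta = 0.25$), and prediction additionally
  returns the codebook index per coarse voxel.

All three satisfy one contract: `seg_predict()` returns a probability grid
at input resolution (mask threshold fixed at 0.5), plus a
`bottleneck_activation` whose coarse grid times the downsample factors
covers the input grid. The 2D models take the pre-contrast, first and
fifth post-contrast series (attention U-Net) or all six series (the
others); examinations must be carried forward to five post-contrast series
first, and a wrong series count is a contract violation.

Weight initialization, fold assignment and training order derive from
explicit seeds, so training is reproducible run-to-run on the same
machine.

## Feature extraction

A coarse voxel is selected when its exactly-counted overlap fraction with
the tumor mask exceeds a threshold (default 0: any overlap). For U-Net-type
models the feature vector holds, per bottleneck channel, the mean,
population standard deviation (divisor $n$, not $n-1$), minimum, maximum
and median over the selected coarse voxels — $K \times 5$ features. For the
vector-quantized model it is the normalized codebook-usage histogram
(length = codebook size, nonnegative, sums to 1). Whether to pool by
statistics or concatenate per-voxel activations is genuinely open; pooling
by statistics keeps the vector length independent of tumor size, which the
downstream modeling requires, and both the statistic set and the mode are
configuration rather than constants.

**Complete radiological response.** A patient in complete response has an
empty post-treatment mask, and nothing to select. The documented fallback
selects the single coarse voxel with the highest predicted tumor
probability; if the probability map is degenerate (constant), it falls
back to global pooling over all coarse voxels. The engaged fallback is
recorded on every feature vector. This choice is deliberate: the
post-treatment features of a complete responder then describe the most
suspicious remaining region, which is the clinically meaningful analogue.

## Modeling choices

* **Variance filter**: drop features with sample variance $< 5\times10^{-4}$
  (a feature exactly at the threshold is kept). Fitted on training rows
  only.
* **Per-set PCA**: centred PCA fitted independently on the pre, post and
  delta sets; retain the smallest number of components reaching 95% of the
  variance (capped at $n-1$), concatenated in set order. The retention rule
  is configuration (`retain`), since per-set component counts admit no
  unique inversion.
* **Random forest**: grid search over trees $\{50, 100, 250\}$ and maximum
  depth $\{2, 3, 5, \text{unlimited}\}$ by 5-fold cross-validation;
  selection criterion is the mean out-of-fold Spearman correlation with
  the RCB score (the study's primary endpoint; mean squared error is
  available). The final model is refitted on all training rows with a
  fixed seed; out-of-fold predictions are kept for training-set
  evaluation.
* **Delta volume sign**: `pre − post`, so shrinkage is positive, matching
  the delta-feature convention.
* **Ensemble**: $\min_w \|Pw - y\|_2^2$ s.t. $w \ge 0$, no intercept
  (Lawson–Hanson). Zero weights are meaningful: a base model can be
  excluded entirely by the data.

## Statistical evaluation

Predicted RCB is a *risk* score: lower predictions indicate
responder/pCR, and every AUC is computed under this orientation
(`direction = "lower"`), recorded in the report. DeLong's
structural-components estimator provides the AUC variance, 95% normal
intervals clipped to $[0,1]$, and the paired two-sided test; when both
models separate perfectly the paired p-value is 1 if the AUCs are equal
and an error otherwise. The cross-validated AUC interval averages per-fold
AUCs and combines per-fold influence-function variances as
$\sum_j \hat\sigma^2_j / J^2$, which reduces exactly to the DeLong interval
at $J = 1$; folds containing a single class are merged into the next fold
with a warning. Kruskal–Wallis p-values use the tie-corrected chi-square
approximation; association p-values are reported unadjusted, and Spearman
correlations with $|\rho| \ge 0.40$ are flagged as moderate/strong.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not MR physics. Per patient: an ellipsoidal tumor (baseline
radius 4–10 mm, per-axis shape jitter) inside a fibroglandular slab on a
$32 \times 32 \times 16$ grid at 2 mm spacing; monoexponential contrast
uptake (tumor amplitude 1.2 with a smooth rim rising towards the edge,
parenchyma 0.25); additive Gaussian image noise (sd 0.02); subtype drawn
from (34%, 37%, 29%) for TN, ER+/HER2− and HER2+; a per-subtype lognormal
shrinkage factor applied to the post-treatment tumor; and a configurable
pCR fraction (default 25%) with an empty post-treatment mask. Anterior-
posterior landmarks are emitted with each examination. The desk-scale grid
and network widths were chosen so that a full 150-patient six-model
comparison runs in minutes on one CPU; all sizes are configuration.

The outcome is generated through pathology: the residual equivalent-sphere
diameter scales $d_{prim}$, subtype and a latent *texture amplitude* shift
the invasive-cellularity logit (noise sd 0.3 by default), nodes are
Poisson, and `rcb_index()` produces the score. With the volume coefficient
set to 1 and everything else off, post-treatment volume and RCB correlate
at $\rho > 0.9$ — the recovery target for the volume baseline. With the
volume coefficient 0 and the texture coefficient driving cellularity, RCB
depends on something volume cannot see — the generator's positive control.

**The texture field.** The latent texture is band-limited noise (three
separable box-blur passes, correlation length about 4 voxels ≈ 8 mm,
standardized) that modulates the contrast-uptake amplitude inside the
tumor — heterogeneous enhancement, the radiological phenotype associated
with aggressive disease. The spatial scale matters: texture far below the
bottleneck's coarse resolution is removed by the pooling path and no
bottleneck feature could recover it, which would make the positive control
vacuous rather than informative.

**Resolution of the positive control.** At desk scale a 4–10 mm tumor
spans only one to three factor-4 coarse blocks, leaving too few
intratumoral samples to estimate a heterogeneity amplitude. The texture
analyses therefore use the 2D attention U-Net with in-plane downsample 2
(`seg_model(..., downsample = 2)`), interior coarse voxels only
(`threshold = 0.5`) and 99% PCA retention — the analogous adaptation real
segmentation pipelines make when object size approaches the bottleneck
grid. With that configuration the deep-feature model reaches held-out
$\rho \approx 0.4$–$0.7$ where the volume baseline hovers near zero,
across seeds.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: MR physics (coil profiles, bias fields — none
are simulated and no bias correction is applied), deformable motion
(inter-series motion is integer-voxel translation; the default
registration backend is FFT phase correlation with subvoxel refinement,
with a rigid mutual-information backend one switch away and an external
backend pluggable as a function), real tumor morphology (ellipsoids with
smooth rims, not spiculated masses), vessels or background parenchymal
enhancement, and DICOM. Results on this generator demonstrate that the
machinery is correct and that the models recover signals the generator
plants; they say nothing about effect sizes in patients.

## Numerical conventions

* Axis 2 ($y$) is anterior-posterior, increasing posteriorly; world
  coordinates are mm; voxel `[1,1,1]` sits at `origin`.
* Crop windows are inclusive of voxel centres; resampling preserves the
  physical field of view within one voxel, trilinear for images and
  nearest-neighbour for masks (masks stay binary).
* The median of an even-length spacing list is the mean of the middle two.
* Dice with both masks empty (within the region of interest) is 1, so
  complete responders are not penalized.
* Region growing includes a voxel when its first-post-contrast relative
  enhancement $(post_1 - pre)/pre$ exceeds the threshold (default 0.5) and
  its geodesic (chamfer) distance through admissible voxels to the nearest
  seed is at most 60 mm; lowering the threshold can only enlarge the mask.
* One global seed fans out to per-stage seeds through a fixed affine map
  modulo $2^{31}-1$, logged in the manifest.

## Known limitations

Training the networks in base R is desk-scale by design; the architectures
are faithful in structure (skips, attention gate, vector quantization) but
not in capacity. The influence-function cvAUC variance assumes
independent folds, which out-of-fold predictions only approximate. The
empty-mask fallback is one defensible convention among several; it is
flagged on every vector so downstream analyses can stratify by it. The
rigid registration backend optimizes mutual information by Nelder–Mead
from a phase-correlation initialization and is intended for small
perturbations, not large rotations.
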