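---
title: "Methods: 2D/3D radiomics for pancreatic cancer detection on CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2D/3D radiomics for pancreatic cancer detection on CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Pancreatic ductal adenocarcinoma typically appears on portal-venous
contrast-enhanced CT as a hypodense, texturally heterogeneous mass inside
the pancreas, but small tumors are frequently missed by visual reading.
`pancrad` implements a computer-aided detection pipeline that classifies a
whole CT study as cancer/no-cancer from a pancreas+tumor segmentation mask
supplied by an upstream segmentation step (segmentation itself is out of
scope; masks are inputs):

1. **3D branch.** The union of pancreas and tumor labels is the volume of
   interest. First-order and gray-level texture features (GLCM, GLRLM,
   GLSZM, GLDM, NGTDM) are computed over the VOI on the original image and
   on filtered images (single-level stationary wavelet bands, a 3 mm
   Laplacian-of-Gaussian), and a gradient-boosted tree classifier maps the
   feature vector to a cancer probability `p3d`.
2. **2D branch.** Each axial slice of the ROI is cropped into 20 x 20 pixel
   patches on a stride-5 lattice; windows whose ROI overlap strictly
   exceeds 5% of the window are valid. A patch-level boosted-tree model
   predicts per-patch cancer probabilities; each heatmap pixel is the mean
   probability of the patches containing it. Pixels above a threshold `t`
   are high-risk; the area (mm^2) of the largest 8-connected in-plane
   region is the branch output `area2d`. `t` is chosen on the validation
   cohort as the grid point (0.05 to 0.95, step 0.01) maximizing the AUC of
   the area statistic.
3. **Fusion.** A logistic regression on validation studies combines the
   branches: `logit(p) = b0 + b1 * p3d + b2 * area2d`. The published
   coefficient set (3.95759716, 0.00241766494, -2.79234888) ships as a
   versioned constant (`paper_fusion_model()`) so the reference operating
   point is directly testable; `b2` is per mm^2, which is why areas are
   computed on the 1 x 1 mm in-plane grid.
4. **Decisions.** Operating cutoffs for `p3d`, `area2d` and the combined
   probability are the maximum-Youden-index points on validation scores
   (candidates are midpoints of adjacent distinct scores plus infinities;
   scores exactly at a cutoff are negative). Series calls (both branches
   positive) maximize specificity; parallel calls (either positive)
   maximize sensitivity.

The statistics layer reports sensitivity/specificity/accuracy with exact
Clopper-Pearson 95% intervals, positive/negative likelihood ratios and
four-cell (3D call x 2D call) likelihood ratios with log-method (Simel)
intervals, Mann-Whitney AUCs with DeLong intervals and the paired DeLong
test, tumor-size-stratified sensitivity (< 2, 2-4, > 4 cm) with a
Cochran-Armitage trend test, and a univariate feature screen (Mann-Whitney
for continuous, Fisher exact for binary features).

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| resampling grid | 1 x 1 x 5 mm, linear (image) / nearest (mask) | canonical analysis grid; all window and area definitions assume it |
| texture bin width | 16 HU, anchored at the region minimum | fixed-bin-width discretization; makes texture features invariant to constant HU shifts |
| patch geometry | 20 x 20 px, stride 5, validity > 5% of 400 px (strict) | fine-grained subregion analysis with 16-fold interior oversampling |
| threshold grid | 0.05–0.95 by 0.01 (91 points), ties to the smallest t | validation-AUC-maximizing pixel threshold |
| early stopping | patience 30 on validation AUC; best iteration kept | both branch models; logistic loss throughout |
| booster defaults | depth 6, eta 0.1, up to 1000 rounds, no subsampling | unexceptional library defaults, recorded in model metadata |
| connectivity | 8-connected within each axial plane | "largest contiguous region among the axial planes" is read per-plane; a 26-connected 3D mode is provided (`connectivity = "3d26"`) but not default |

## The phantom generator

No patient imaging ships with (or is downloadable by) this package, so
`phantom_spec()`/`generate_cohort()` produce seeded synthetic cohorts the
whole pipeline can be trained and tested on. Each study is an
ellipsoidal, smoothly deformed "gland" (~100 HU) in a soft-tissue
background; tumors are spheres intersected with the gland (so the tumor is
always a subset of the segmentation union), with diameters drawn
log-normally around 2.5 cm, clamped to 8–45 mm, and stratified at the
clinical < 2 / 2–4 / > 4 cm cuts from the drawn (maximum) diameter.

The texture model is deliberately minimal: the gland carries a smoothly
correlated random field (12 HU sd, 5 mm correlation length) plus 1 HU
voxel-scale scanner noise; tumor voxels are shifted -25 HU and receive a
5x multiplier on the voxel-scale noise. These values were chosen so the
generated patches reproduce the qualitative feature directions reported
for real tumors — NGTDM busyness higher and first-order median lower in
cancerous patches — at attenuation differences typical for pancreatic
adenocarcinoma in the portal-venous phase. An earlier draft used
broad-band white noise for tumor heterogeneity; that *lowers* NGTDM
busyness (a wide histogram inflates the busyness denominator), which is
why heterogeneity is modeled as amplified voxel-scale noise instead. HU
values are quantized to integers, as CT storage does. Gland and
background fields are drawn before any tumor-specific randomness, so a
case and a control generated from the same seed share the gland exactly
and differ only by the inserted tumor.

What the phantom does **not** emulate: anatomy beyond a single gland-like
blob, scanner/kernel variation across vendors, contrast-phase timing,
partial-volume and beam-hardening artifacts, infiltrative (gradual) tumor
margins, and non-tumorous pancreatic disease. Passing the end-to-end
phantom experiment therefore demonstrates that the pipeline is wired
correctly and can learn a planted hypodense/heterogeneous signal — not
that it reaches any particular accuracy on clinical images.

## Numerical choices and degenerate inputs

* Resampled grid size per axis is `round(extent / target_spacing)`;
  coordinates are voxel centers with the origin fixed, out-of-field reads
  clamp to the border. Resampling onto the native grid is the identity.
* Texture matrices follow the IBSI-style definitions; GLCM/GLRLM features
  are computed per angle (4 in 2D, 13 in 3D) and averaged over angles with
  nonzero counts. GLDM uses dependence size = dependent neighbors + 1 so
  small-dependence emphasis never divides by zero.
* Degenerate regions: GLCM correlation falls back to 1 on zero gray-level
  variance, NGTDM coarseness to 1e6 and busyness to 0 on zero
  denominators, skewness to 0 for constant regions; an empty ROI produces
  the documented fallback vector with a `degenerate` flag, and an empty
  post-resampling segmentation excludes the study with a logged record.
* Wavelet: coif1, single level, undecimated, symmetric padding, analysis
  gain sqrt(2) per axis. LoG: separable convolution with the sampled
  analytic kernel (sigma in mm), truncated at 4 sigma, reflect padding.
* Filters are applied to the full slice/volume once and windows are
  cropped afterwards, so overlapping patches share filtered content.
* The feature manifest is configuration, not a fixed list: the historical
  feature counts of the original models (1183 features in 3D, 545 in 2D —
  the source reports both 545 and 546) are not reconstructible from the
  publication, so correctness is defined by names and ordering. The
  default 3D manifest has 290 features (original + LoG-3mm + 8 wavelet
  bands, 29 features each); the default 2D manifest has 145 (original + 4
  wavelet bands).
* Perfect separation in the fusion fit (common on small, clean validation
  cohorts) is detected and refit with a light ridge penalty, flagged via
  `separation = TRUE`; with a perfectly separating area statistic the 3D
  coefficient is then essentially unidentified and may sit at ~0.
* The Youden cutoff, binarization and decision rules all use strict `>`;
  ties in the threshold search resolve to the smallest threshold.
* The trend test over size strata is Cochran-Armitage with equally spaced
  scores (the method is a package choice; a flat 0%/100% detection profile
  has no trend information and returns NA). Pairwise sensitivity
  comparisons between analyses use exact McNemar on discordant pairs —
  also a package choice, flagged in the function documentation.
* DICOM support covers uncompressed little-endian series (explicit and
  implicit VR, 16-bit monochrome); HU = slope x stored + intercept per
  slice. Anything else raises a format error; NIfTI is the primary format.

## Problem sizes used in the shipped experiments

The standing end-to-end experiment trains on 150 phantom studies (90
train / 60 validation, balanced classes) and evaluates on 100 held-out
studies on 84 x 56 x 10 voxel volumes; with the default manifests this
produces roughly 60k patch feature rows and runs in a few minutes on one
CPU. These sizes are the package's reference conditions: they are large
enough for both branch models to reach stable test AUCs above 0.9 while
keeping the experiment quick to reproduce (`run_phantom_experiment()`,
also executed by `scripts/acceptance.R`). Statistical calibration checks
(interval coverage, null AUC, trend-test level) run at 500–2000
replicates with fixed seeds.

## Known limitations

* Feature formulas cover the families and features named in the model
  rankings plus common companions (29 per filter), not the full catalogue
  of any extraction platform; numerical parity with a specific platform is
  not claimed (aggregation conventions differ between platforms anyway).
* Whether 2D features should use 2D or 3D LoG filtering is ambiguous in
  the source description; the 2D manifest omits LoG by default and
  in-plane LoG is available by adding `log-sigma-<s>-mm` to a 2D manifest.
* The per-plane reading of "largest contiguous region" cannot be ruled
  out to differ from the original; the 3D-linked alternative is one
  configuration flag away.
* Likelihood-ratio intervals use the log method with zero-cell sentinels
  (0 or Inf with one-sided bounds) rather than continuity corrections.
* The phantom's simplicity means phantom AUCs saturate near 1; they
  demonstrate learnability and wiring, not clinical performance.
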