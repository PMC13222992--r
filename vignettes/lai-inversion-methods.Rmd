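---
title: "Methods: LAI inversion from UAV RGB time series"
author: "uavlai"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LAI inversion from UAV RGB time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(uavlai)
```

## The problem

Leaf area index (LAI, one-sided green leaf area per unit ground area,
m²/m²) is the canopy variable that water, fertilizer and yield decisions in
orchard management hinge on. Field instruments measure it point by point;
UAV RGB imagery covers whole blocks at centimetre resolution but measures
only visible-band radiance. `uavlai` implements an inversion chain from
multi-date RGB canopy imagery to LAI: radiometric calibration, cross-date
normalization, spectral/texture feature engineering, statistical feature
screening, label-mixing augmentation, a hybrid neural regressor over the
phenological time series, a leakage-safe evaluation protocol, and map
production scored with spatial quality metrics.

Because consumer RGB cameras lack a near-infrared band, none of the
NIR-based indices (NDVI and relatives) are available; the feature set is
built entirely from R, G, B and their combinations, complemented by image
texture.

## The synthetic benchmark

No field data ships with the package. Instead, a seeded generator
(`scene_config()`, `generate_orchard_scene()`,
`generate_time_series_dataset()`) renders orchard scenes with the
statistical structure the inversion assumes, so every stage of the chain is
testable end to end:

* **Layout** — elliptical canopies on a regular row grid over bare-soil
  background. Defaults follow a wide-row, narrow-plant pattern (4.5 m row,
  1.5 m plant spacing) at 0.83 cm/pixel ground resolution.
* **Greenness link** — the expected canopy green reflectance is a strictly
  increasing logistic function of the local true LAI, rising from 0.15 to
  0.55 across the LAI range. This monotone link is what makes the problem
  solvable from greenness at all, and is asserted by tests.
* **Texture link** — zero-mean Gaussian-blob texture inside each canopy
  whose amplitude is proportional to LAI, giving the co-occurrence
  statistics a signal to carry.
* **Phenology** — each sampling point follows a logistic LAI trajectory
  over L = 3 named stages (growth, maturity, fruit-bearing) with a
  point-level random intercept (sigma 0.12 LAI); the final-stage value, drawn
  uniformly from [3.3, 5.2], is the label.
* **Camera and illumination** — reflectance maps to digital numbers
  through DN = 255 · reflectance^0.8, with additive DN noise (sd 1), and
  each acquisition date applies a global gain (0.9–1.1) and bias (−8 to
  +8) in DN space. The gain/bias is the minimal artifact that the
  histogram-matching normalization must remove; the power-law response is
  what panel calibration must invert.
* **Panel** — a 24-step grayscale chart imaged through the same camera
  model anchors the calibration.

All randomness flows through one seeded generator per call; the same
config and seed reproduce bit-identical rasters, and no exported function
touches the caller's RNG state.

What the generator does **not** emulate: perspective and stitching
artifacts, cast shadows and sun geometry, mixed understory vegetation,
wind-blurred textures, and any radiative-transfer realism. Passing the
synthetic-recovery tests therefore demonstrates that the chain is
implemented correctly and recovers planted structure — not that the same
accuracy would be reached on real orchards.

## Preprocessing

**Radiometric response.** The DN-to-reflectance curve is fitted per band
as a monotone piecewise-linear interpolant through the panel knots,
clamped to the end reflectances outside the fitted domain
(`fit_radiometric_response()`). Piecewise linearity is chosen over
polynomials because it is exact at the knots, guaranteed monotone and
cannot oscillate. Its interpolation error between knots vanishes as the
panel step shrinks; the round-trip test uses a dense panel to verify the
inversion to 1e-6.

**Histogram matching** (`histogram_match()`) removes residual cross-date
radiometric drift: each date's per-band empirical distribution is mapped
onto the reference date's (the first flight). 8-bit integer inputs use a
256-bin CDF lookup; float inputs use exact quantile mapping. In the sample
pipeline the mapping is computed on the pixels of all patches of a date
pooled together, so one monotone map is applied per (date, band).

**Normalization.** Min-max statistics are fitted on training rows only and
applied everywhere; constant features map to 0 and out-of-range test
values are deliberately not clamped (an out-of-range value is signal).
Labels are standardized internally for the neural optimizer and predictions
mapped back, so the linear output unit starts near the optimum.

**Missing timesteps** (`fill_missing_timesteps()`): one interior gap is
filled by the per-feature mean of its two neighbouring stages; one edge
gap takes the nearest present stage (the generator's stages are close
enough in time that nearest-value extrapolation is the conservative
choice); samples missing more than one of the three stages are rejected.

## Features

`compute_spectral_features()` produces the 26 spectral parameters: the
three band values and 23 visible-band indices (chromatic coordinates,
band ratios, normalized differences, excess-colour composites, IPCA, CIVE,
simple differences, the band mean and the coloration index). Band means
over the patch are computed first and indices evaluated on the three means
(one vector per patch), which matches sampling-point-level modelling;
per-pixel evaluation is available behind `aggregation = "pixelwise"`.
Any ratio with a zero denominator evaluates to 0 and increments a
per-feature degeneracy counter, keeping vectors finite and auditable (the
normalized difference index carries its own +0.01 guard).

`compute_glcm()` quantizes a window to Ng = 32 equal-width levels over the
window's observed range (so all statistics are invariant to adding a
constant to every pixel), accumulates symmetric co-occurrence counts at
the displacement vector — the default "2 × 2" is the diagonal offset
(2, 2) — and normalizes. `compute_texture_features()` evaluates the eight
Haralick statistics (mean, variance, homogeneity, contrast, dissimilarity,
entropy, second moment, correlation) with 0-based level indices, natural
log entropy, 0·log 0 := 0, and correlation defined as 0 when a marginal
standard deviation vanishes. Texture for a patch is the average of the
statistics over a non-overlapping tiling of 9 × 9 windows (a patch smaller
than the window uses one whole-patch window). At the default 0.83 cm/pixel
the 9-pixel window spans 7.47 cm — the scale of a mature jujube leaf — and
the 2-pixel displacement spans 1.66 cm.

The full candidate set is 26 spectral + 8 × 3 texture = 50 features with a
stable documented order. `texture_sensitivity_sweep()` evaluates the
feature–LAI correlations over the window sizes {3, 5, 7, 9, 11} and
displacements {1, 2, 3}; the one geometrically empty setting (3 × 3 window
with a 3-pixel offset admits no pixel pair) is reported with NA rather
than silently dropped.

## Screening

Two-step optimization (`screen_features()`):

1. **Correlation screen** — a feature is eliminated only when |r| with LAI
   is strictly below 0.10 in *every* stage; reaching 0.10 in any one stage
   retains it.
2. **VIF elimination** — iteratively remove the single feature with the
   highest variance inflation factor strictly above 10 (VIF = 1/(1−R²) of
   the feature regressed, with intercept, on its co-features; exact
   collinearity is an infinite sentinel), recomputing after each removal.
   Ties break to the earliest column for reproducibility.

Retained features are then verified by partial correlation against LAI,
controlling for the other retained features through least-squares
residualization. Residual variance at floating-point noise level is
treated as full explanation (partial r = 0, flagged degenerate).

## CutMix augmentation

`cutmix()` transplants one axis-aligned rectangle, covering 40% of the
patch area by default, from a donor sample into a base sample at a
uniformly random location, using the same region across all L stage
patches. The rectangle's aspect ratio is constrained to [0.5, 2]; among
admissible heights the height/width pair nearest the target pixel area is
drawn, so the realized area differs from the request only by pixel
quantization. The mixed label is the area-weighted combination
yc = (1 − λ)·ya + λ·yb with λ the *realized* pixel fraction — at 40% donor
area the base label keeps its 60% weight. Feature-mode pipelines recompute
features from the mixed patches, keeping the area-weighted label
physically meaningful (LAI is itself an area-weighted quantity).
Augmentation applies to training data only; synthetic samples carry both
parents' point IDs so the protocol can prove they never cross the
train/test boundary. The number of synthetic samples defaults to one per
training sample (doubling the training set); the fraction is a config
parameter.

## The hybrid regressor

`build_cnn_gru()` wires two parallel branches into a meta-learner:

* **CNN branch** — three convolution blocks of 64, 128, 256 filters
  (kernel 3) with ReLU and stride-2 max pooling, then spatial dropout
  (rate 0.2), flatten, and a 64-unit dense branch head. In feature mode
  the convolution is 1-D along the feature-field axis of the F × L input
  matrix with the L stages as channels; in image mode it is 2-D over the
  per-stage patch stack (3L channels).
* **GRU branch** — two stacked gated recurrent layers of 128 and 64 units
  consume the L = 3 stage vectors in order, then a 64-unit dense head.
* **Meta-learner** — the concatenated branch outputs pass through 128- and
  64-unit dense layers into a single linear output.

Both input modes are implemented because the screening-driven pipeline
naturally works on the F × L matrix while the input-size study requires
resized images; each experiment declares its mode. The branch heads are
single 64-unit layers — the smallest head that gives each branch its own
nonlinear read-out.

Training uses Adam (initial learning rate 0.001), batch size 32, MSE loss,
and early stopping (patience 20) on a 10% validation split carved from the
training data, up to 500 epochs by default; the tests and the acceptance
experiments use 150 epochs with patience 15, which the validation curves
show is past the early-stopping point at these problem sizes. All
initialization, shuffling and dropout randomness derives from the config
seed, making training runs bit-reproducible on one platform.

The engine behind these models (dense, 1-D/2-D convolution, max pooling,
spatial dropout, GRU, layer normalization, multi-head self-attention,
Adam) is implemented in the package on base-R arrays with hand-derived
backward passes; every layer's gradient is checked against central finite
differences in the test suite.

**Baselines** (`build_baseline()`): a small Transformer encoder (2 layers,
4 heads, width 64, the L timesteps as tokens — the smallest credible
encoder), distance-weighted k = 5 nearest neighbours, a two-hidden-layer
(128, 64) MLP, the CNN branch alone, random forest (500 trees, via
randomForest) and gradient boosting (500 rounds, learning rate 0.05,
depth 6, via xgboost). All consume the same normalized inputs.

## Evaluation protocol

`split_samples()` divides at the sampling-point level by default: whole
points accumulate, in seeded random order, until the training sample count
is nearest 80% of N, so no point ever contributes to both sides.
`kfold_by_point()` partitions points into folds differing by at most one
point. `repeated_evaluation()` fixes the split once and repeats
training with fresh initialization and augmentation, reporting per-metric
mean, SD, and a 95% percentile bootstrap interval over the per-repeat
values (a deterministic model yields a zero-width interval).
`paired_bootstrap_test()` resamples paired residual indices 1000 times;
the one-sided p is the fraction of resamples where the claimed-better
model's mean squared residual fails to beat the other's, ties counted
against the claim. Metrics are R² = 1 − SSres/SStot, RMSE (LAI units),
MAE, MAPE (%), and rRMSE = RMSE/mean(y)·100.

`input_size_study()` sweeps image-mode input sizes (supported: 16–224 px)
and reports per-size accuracy plus pixel-count ratios (224² is 196× 16²).

## Maps and spatial metrics

`sliding_window_map()` tiles the multi-date scene, builds a temporal
sample per tile, predicts, and writes each prediction onto its footprint
(overlaps averaged, edges covered by reflection padding). Map quality:

* **Moran's I** — global autocorrelation under row-standardized queen (or
  rook) contiguity; +1 smooth, −1 perfectly alternating.
* **SSIM** — mean local structural similarity, 7 × 7 uniform window,
  stabilizers K1 = 0.01, K2 = 0.03 with the reference's dynamic range.
* **CV** — population SD over mean.
* **Spatial entropy** — Shannon entropy (natural log) of the 64-bin
  equal-width histogram over the map's range.

Neighbourhood scheme, window, stabilizers and bin count are not forced by
any single convention; they are fixed to these widely used defaults and
exposed in the function arguments. Natural-log entropy over dozens of
occupied bins gives values in the low units for realistic maps.

## Numerical choices and degenerate inputs

* Division by zero in spectral indices → 0 plus a degeneracy counter.
* GLCM of a constant window → all mass at one level pair; entropy 0,
  second moment 1, correlation 0.
* Pearson r of a constant column → 0 with a degeneracy flag.
* R² is undefined (flagged NA) when the observed labels have zero
  variance; MAPE is guarded against |y| < 1e-9.
* Non-finite training or validation loss aborts training with a
  diagnostic rather than returning a broken model.
* Moran's I of a constant map → NA with an `undefined` attribute;
  CV of a zero-mean map is an error.

## Problem sizes used by the shipped experiments

The synthetic-recovery experiment runs 300 sampling points × 3 stages
(48 px patches at the default camera model), screens the 50 candidate
features, doubles the training side by CutMix, and trains the hybrid for
up to 150 epochs — a few minutes on one CPU. The screening study uses
1000 samples per stage over repeated seeds, which puts the null
correlation noise (≈ 0.032 SD) far below the 0.10 threshold. The mapping
test uses a densely planted block so that every map tile carries canopy
signal; in a sparse wide-row layout most tiles are bare soil whose
nearest-point "truth" is not recoverable from tile pixels, which is a
property of the layout, not of the method.

## Known limitations

* The engine is plain R: fine at these problem sizes, not meant for
  224-px image stacks at thousands of samples.
* The generator's greenness link is monotone by construction; real
  canopies saturate and senesce, so real-data accuracy cannot be inferred
  from the synthetic benchmark.
* Histogram matching assumes the scene composition is comparable across
  dates; strong phenological change violates that assumption and the
  matching then removes real signal along with illumination drift.
* The transformer baseline is intentionally minimal and underperforms on
  small samples, consistent with its role as a comparison point.
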