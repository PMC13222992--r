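# uavlai

Inversion of orchard leaf area index (LAI, m²/m²) from multi-temporal UAV
RGB imagery, for crop-phenotyping and precision-orchard work where only a
visible-band camera is available. The package covers the whole chain:

- **Synthetic orchard benchmark** — a seeded generator renders elliptical
  canopies over soil with a strictly monotone greenness–LAI link,
  LAI-coupled texture, logistic per-point LAI trajectories over the three
  phenological stages, a nonlinear camera response (DN = a·ρ^γ) and
  per-date illumination gain/bias, so the pipeline is testable without
  field data.
- **Preprocessing** — panel-based radiometric calibration (monotone
  piecewise-linear DN → reflectance), cross-date histogram matching,
  train-only min-max normalization, missing-timestep interpolation.
- **Features** — 26 RGB spectral parameters (chromatic coordinates, band
  ratios, normalized differences, excess-colour indices, IPCA, CIVE, band
  differences, MRGB, CI) and 8 gray-level co-occurrence (GLCM) texture
  statistics per band at a 9 × 9 window with a (2, 2) displacement.
- **Screening** — per-stage Pearson filter (|r| < 0.10 in *all* stages
  eliminates), iterative VIF elimination (> 10), partial-correlation
  verification.
- **CutMix for regression** — rectangle transplant between training
  patches with the label mixed by realized area,
  y_c = (1 − λ)·y_a + λ·y_b (λ = 0.40 by default, so the base label keeps
  60%).
- **Model** — a parallel CNN-GRU hybrid: a convolutional branch
  (64/128/256 filters, kernel 3, spatial dropout) over the feature-field
  axis (or the resized per-stage image stack), a two-layer GRU (128, 64
  units) over the L = 3 stages, fused by a dense meta-learner (128, 64 → 1).
  Trained with Adam (lr 0.001), batch 32, early stopping. Baselines:
  Transformer, KNN, MLP, CNN, random forest, XGBoost.
- **Evaluation** — sampling-point-level 80/20 splits (no point on both
  sides), point-level 10-fold CV, repeated runs with mean ± SD and 95%
  bootstrap CIs, paired bootstrap significance tests, input-size study.
- **Maps** — sliding-window LAI maps scored by Moran's I, SSIM,
  coefficient of variation and spatial entropy.

The neural-network engine (convolutions, GRU, attention, Adam, backprop)
is implemented in the package itself on base-R arrays; every layer's
gradient is verified against finite differences in the test suite.

## Worked example

Generate a labelled synthetic orchard, run the full inversion, and look at
the held-out accuracy:

```r
library(uavlai)

cfg <- scene_config(n_points = 80, seed = 11)      # 80 points, 3 stages
res <- run_lai_pipeline(config = cfg,
                        model_cfg = model_config(max_epochs = 100,
                                                 patience = 12, seed = 2),
                        augment = TRUE, split_seed = 4)

length(res$retained)
#> [1] 18
res$retained[1:6]
#> [1] "WI"    "MRGB"  "MEA_R" "HOM_R" "CON_R" "ENT_R"
sprintf("held-out R2 %.3f RMSE %.3f (train %d / test %d)",
        res$metrics$r2, res$metrics$rmse, res$n_train, res$n_test)
#> [1] "held-out R2 0.881 RMSE 0.207 (train 128 / test 16)"
```

The screening report explains every elimination — e.g. the raw `R` and `B`
bands fall to the correlation filter (|r| < 0.10 with LAI at every stage)
while the mutually redundant chromatic coordinates fall to the VIF filter:

```r
head(res$screening[, c("feature", "max_abs_r", "retained", "reason")], 5)
#>   feature max_abs_r retained                    reason
#> 1       R    0.0902    FALSE |r| < 0.10 in all stages
#> 2       G    0.9605    FALSE              VIF Inf > 10
#> 3       B    0.0824    FALSE |r| < 0.10 in all stages
#> 4     RCC    0.9834    FALSE              VIF Inf > 10
#> 5     GCC    0.9864    FALSE              VIF Inf > 10
```

Here 18 of the 50 candidate features survive screening; the hybrid model
then predicts held-out LAI (range 3.3–5.2) with an R² of 0.88 and an RMSE
of about 0.2 m²/m² on this small benchmark.

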