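test_that("Moran's I matches the brute-force double sum and known cases", {
  # 4x4 checkerboard under rook weights: perfect alternation -> -1
  cb <- outer(1:4, 1:4, function(r, c) (-1)^(r + c))
  expect_equal(morans_i(cb, weights = "rook"), -1)
  # smooth gradient: positive autocorrelation
  grad <- outer(1:8, 1:8, `+`)
  expect_gt(morans_i(grad), 0)
  # oracle equivalence on random maps, both weight schemes
  set.seed(21)
  for (i in 1:8) {
    m <- matrix(rnorm(30), 5, 6)
    expect_equal(morans_i(m, "queen"), oracle_morans_i(m, rook = FALSE),
                 tolerance = 1e-12)
    expect_equal(morans_i(m, "rook"), oracle_morans_i(m, rook = TRUE),
                 tolerance = 1e-12)
  }
  # permutation null: mean over random relabelings approaches -1/(n-1)
  m <- matrix(rnorm(36), 6, 6)
  perms <- vapply(1:300, function(i)
    morans_i(matrix(sample(as.vector(m)), 6, 6)), numeric(1))
  expect_lt(abs(mean(perms) - (-1 / 35)), 0.02)
  # zero variance -> undefined flag
  flat <- morans_i(matrix(1, 3, 3))
  expect_true(is.na(flat) && isTRUE(attr(flat, "undefined")))
})

test_that("SSIM is 1 on self, punishes inversion, matches the oracle", {
  set.seed(22)
  x <- matrix(runif(64, 3, 5), 8, 8)
  expect_equal(ssim_map(x, x), 1)
  inv <- -x + 8
  expect_lt(ssim_map(inv, x), ssim_map(x, x))
  y <- x + matrix(rnorm(64, 0, 0.2), 8, 8)
  expect_equal(ssim_map(y, x), oracle_ssim(y, x), tolerance = 1e-10)
  expect_error(ssim_map(x, matrix(1, 4, 4)), "shape")
})

test_that("spatial CV and entropy behave on degenerate and closed forms", {
  expect_equal(spatial_cv(matrix(4, 3, 3)), 0)
  expect_equal(spatial_cv(matrix(c(3, 5), 1, 2)), 0.25)   # SD 1, mean 4
  m <- matrix(runif(25, 1, 2), 5, 5)
  expect_equal(spatial_cv(m * 3), spatial_cv(m), tolerance = 1e-12)
  expect_error(spatial_cv(matrix(c(-1, 1), 1, 2)), "zero-mean")

  expect_equal(spatial_entropy(matrix(7, 4, 4)), 0)
  # uniform over exactly 4 occupied bins
  v <- matrix(rep(c(0, 1, 2, 3), 4), 4, 4)
  expect_equal(spatial_entropy(v, bins = 4L), log(4))
  for (i in 1:5) {
    r <- matrix(runif(100), 10, 10)
    expect_lte(spatial_entropy(r, bins = 64L), log(64))
  }
})

test_that("mean-filter smoothing raises Moran's I and lowers entropy", {
  # maps large enough that the 64-bin histogram is populated; on very
  # small maps the binned entropy is dominated by sampling noise
  set.seed(23)
  for (i in 1:50) {
    m <- matrix(runif(400), 20, 20)
    sm <- smooth_map(m)
    expect_gte(morans_i(sm), morans_i(m))
    expect_lte(spatial_entropy(sm), spatial_entropy(m))
  }
})

# Temporal tile samples cut from a scene bundle at given offsets, labelled
# with the tile-mean of the final-stage truth field.
tiles_from_bundle <- function(bundle, curve, offsets, window) {
  scenes <- lapply(bundle$scenes, apply_radiometric_calibration,
                   curve = curve)
  lapply(seq_len(nrow(offsets)), function(i) {
    r0 <- offsets$r[i]; c0 <- offsets$c[i]
    ri <- r0:(r0 + window - 1L); ci <- c0:(c0 + window - 1L)
    patches <- lapply(scenes, function(sc) sc[ri, ci, , drop = FALSE])
    structure(list(point_id = i, patches = patches,
                   present = rep(TRUE, length(patches)),
                   lai = mean(bundle$truth_field[[length(scenes)]][ri, ci]),
                   synthetic = FALSE, parent_points = i),
              class = "temporal_sample")
  })
}

test_that("sliding-window maps recover the synthetic truth field", {
  # per-date illumination held at identity: the mapping property is tested
  # on a calibrated, radiometrically consistent pair of scenes
  # a fully planted dense block (one canopy per 24 px cell) so every map
  # tile carries canopy signal; the scene side is a multiple of the window
  mk_cfg <- function(seed) tiny_scene_config(
    n_points = 144L, patch_px = 24L, seed = seed, scene_size = c(312L, 312L),
    row_spacing_m = 1.2, plant_spacing_m = 1.2,
    gain_range = c(1, 1), bias_range = c(0, 0))
  cfg <- mk_cfg(31L)
  panel <- generate_panel_observations(cfg)
  curve <- fit_radiometric_response(panel)
  fcfg <- feature_config(features = c("MRGB", "GCC", "EXG", "G", "MEA_G",
                                      "CON_G", "ENT_G"),
                         glcm_window = 9L, glcm_levels = 16L)
  # training tiles are random crops of an independent scene from the same
  # generator, so the model sees the same canopy/soil tile mixture the
  # sliding window will produce
  train_bundle <- generate_orchard_scene(mk_cfg(77L))
  set.seed(41)
  offs <- data.frame(r = sample.int(312L - 23L, 150L, replace = TRUE),
                     c = sample.int(312L - 23L, 150L, replace = TRUE))
  train_tiles <- attach_sample_features(
    tiles_from_bundle(train_bundle, curve, offs, 24L), fcfg)
  mc <- model_config(max_epochs = 60L, patience = 10L,
                     filters = c(16L, 24L, 32L), gru_units = c(32L, 16L),
                     branch_units = 16L, head_units = c(32L, 16L), seed = 7L)
  fit <- train_model(build_cnn_gru(mc), train_tiles)

  bundle <- generate_orchard_scene(cfg)
  scenes <- lapply(bundle$scenes, apply_radiometric_calibration, curve = curve)
  map <- sliding_window_map(fit, scenes, window = 24L, stride = 24L,
                            feature_cfg = fcfg, cell_size_cm = cfg$resolution)
  expect_identical(dim(map$grid), c(312L, 312L))
  expect_true(all(is.finite(map$grid)))
  # non-overlapping tiling writes each cell exactly once: block-constant map
  expect_equal(length(unique(as.vector(map$grid))),
               length(unique(as.vector(map$grid[seq(1, 312, 24),
                                                seq(1, 312, 24)]))))
  # tile-mean prediction vs tile-mean truth
  truth <- bundle$truth_field[[3]]
  starts <- seq(1L, 312L - 23L, by = 24L)
  pred_t <- c(); true_t <- c()
  for (r in starts) for (cc in starts) {
    pred_t <- c(pred_t, mean(map$grid[r:(r + 23), cc:(cc + 23)]))
    true_t <- c(true_t, mean(truth[r:(r + 23), cc:(cc + 23)]))
  }
  expect_gte(regression_metrics(true_t, pred_t)$r2, 0.6)
  # a pixelwise shuffle of the map loses its spatial continuity
  shuffled <- matrix(sample(as.vector(map$grid)), 312, 312)
  expect_gt(morans_i(map$grid), morans_i(shuffled))
  # constant-predicting model gives a constant map
  const_fit <- fit
  const_fit$name <- "knn"
  const_fit$fit <- list(X = matrix(0, 1, 21), y = 4.2, k = 1L)
  cmap <- sliding_window_map(const_fit, scenes, window = 160L, stride = 160L,
                             feature_cfg = fcfg)
  expect_true(all(cmap$grid == 4.2))
  expect_error(sliding_window_map(fit, scenes, window = 400L), "exceeds")
})
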