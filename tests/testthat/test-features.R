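uniform_patch <- function(r, g, b, px = 4L) {
  p <- array(0, c(px, px, 3))
  p[, , 1] <- r; p[, , 2] <- g; p[, , 3] <- b
  p
}

test_that("spectral parameters match their formulas on forced cases", {
  v <- compute_spectral_features(uniform_patch(100, 100, 100))
  expect_length(v, 26L)
  expect_identical(names(v), uavlai:::spectral_feature_names)
  expect_equal(unname(v[c("RCC", "GCC", "BCC")]), rep(1 / 3, 3))
  expect_equal(unname(v["GRVI"]), 0)
  expect_equal(unname(v["EXG"]), 0)
  expect_equal(unname(v["GRRI"]), 1)
  expect_equal(unname(v["MRGB"]), 100)
  expect_equal(unname(v["SDRG"]), 0)

  g <- compute_spectral_features(uniform_patch(0, 255, 0))
  expect_equal(unname(g["GCC"]), 1)
  expect_equal(unname(g["EXG"]), 2)
  expect_equal(unname(g["GRVI"]), 1)
  expect_equal(unname(g["WI"]), (255 - 0) / (0 - 255))

  blk <- compute_spectral_features(uniform_patch(0, 0, 0))
  expect_equal(unname(blk["CIVE"]), 18.78745)
  expect_equal(unname(blk[c("RCC", "GCC", "BCC")]), c(0, 0, 0))
  expect_error(compute_spectral_features(array(1, c(0, 2, 3))), "non-empty")
})

test_that("chromatic indices are scale-invariant; differences scale linearly", {
  set.seed(3)
  p <- array(runif(4 * 4 * 3, 20, 200), c(4, 4, 3))
  v1 <- compute_spectral_features(p)
  v2 <- compute_spectral_features(p * 3.7)
  inv <- c("RCC", "GCC", "BCC", "GRRI", "GBRI", "RBRI", "GRVI", "NDI", "WI",
           "IKAW", "GLI", "VARI", "EXR", "EXG", "EXB", "CI")
  expect_equal(v1[inv], v2[inv], tolerance = 1e-12)
  lin <- c("MRGB", "SDGB", "SDRB", "SDRG", "SGRB", "IPCA")
  expect_equal(unname(v2[lin]), unname(v1[lin]) * 3.7, tolerance = 1e-12)
})

test_that("GLCM accumulates symmetric pair counts", {
  g <- compute_glcm(matrix(c(0, 1, 0, 1), 2, 2), levels = 2L,
                    displacement = c(0L, 1L))
  expect_equal(g$P, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(sum(g$P), 1)
  expect_equal(g$P, t(g$P))
  # constant window: single occupied cell
  gc <- compute_glcm(matrix(5, 3, 3), levels = 4L, displacement = c(1L, 1L))
  expect_equal(gc$P[1, 1], 1)
  expect_error(compute_glcm(matrix(1:4, 2, 2), levels = 2L,
                            displacement = c(2L, 2L)), "smaller than")
})

test_that("texture statistics match direct evaluation and brute force", {
  P <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  v <- compute_texture_features(P)
  expect_equal(unname(v["CON"]), 0)
  expect_equal(unname(v["SEC"]), 0.5)
  expect_equal(unname(v["ENT"]), log(2))
  expect_equal(unname(v["HOM"]), 1)
  expect_equal(unname(v["DIS"]), 0)
  # degenerate single-entry distribution
  single <- matrix(0, 3, 3); single[2, 2] <- 1
  vs <- compute_texture_features(single)
  expect_equal(unname(vs["ENT"]), 0)
  expect_equal(unname(vs["SEC"]), 1)
  expect_equal(unname(vs["COR"]), 0)    # zero marginal SD policy
  # uniform over 4 cells
  vu <- compute_texture_features(matrix(0.25, 2, 2))
  expect_equal(unname(vu["ENT"]), log(4))
  expect_equal(unname(vu["SEC"]), 0.25)

  # oracle equivalence on random small windows
  set.seed(11)
  for (i in 1:20) {
    h <- sample(3:4, 1); w <- sample(3:4, 1)
    win <- matrix(sample(0:50, h * w, replace = TRUE), h, w)
    disp <- c(sample(0:2, 1), sample(0:2, 1))
    if (disp[1] >= h || disp[2] >= w || all(disp == 0)) next
    lev <- sample(2:6, 1)
    g <- compute_glcm(win, lev, disp)
    expect_equal(g$P, oracle_glcm(win, lev, disp), tolerance = 1e-15)
    expect_equal(compute_texture_features(g), oracle_haralick(g$P),
                 tolerance = 1e-12)
  }
})

test_that("GLCM statistics are invariant to adding a constant to all pixels", {
  set.seed(7)
  win <- matrix(runif(81, 0, 1), 9, 9)
  cfg <- feature_config()
  g1 <- compute_texture_features(compute_glcm(win, 32L, c(2L, 2L)))
  g2 <- compute_texture_features(compute_glcm(win + 123.4, 32L, c(2L, 2L)))
  expect_equal(g1[c("CON", "DIS", "HOM", "ENT", "SEC")],
               g2[c("CON", "DIS", "HOM", "ENT", "SEC")], tolerance = 1e-12)
})

test_that("window footprint converts pixels to ground distance", {
  expect_equal(window_footprint(9, 0.83), 7.47)
  expect_equal(window_footprint(2, 0.83), 1.66)
  expect_equal(window_footprint(1, 1.0), 1.0)
  expect_error(window_footprint(0, 1), "positive")
})

test_that("patch feature extraction honours the configured subset and order", {
  set.seed(9)
  p <- array(runif(20 * 20 * 3, 0, 1), c(20, 20, 3))
  full <- extract_patch_features(p, feature_config())
  expect_length(full, 50L)
  expect_identical(names(full), all_feature_names())
  sub <- feature_config(features = c("MRGB", "ENT_G", "GCC"))
  v <- extract_patch_features(p, sub)
  expect_identical(names(v), c("MRGB", "ENT_G", "GCC"))
  expect_equal(v[["MRGB"]], full[["MRGB"]])
  expect_error(feature_config(features = "NDVI"), "unknown feature")
  # patch smaller than the GLCM window: single whole-patch window
  small <- array(runif(5 * 5 * 3), c(5, 5, 3))
  vs <- extract_patch_features(small, feature_config())
  expect_true(all(is.finite(vs)))
})

test_that("sensitivity sweep covers the window/displacement grid", {
  cfg <- tiny_scene_config(n_points = 10L, seed = 3L)
  d <- generate_time_series_dataset(cfg)
  tab <- texture_sensitivity_sweep(d, windows = c(3L, 5L), displacements = 1:2,
                                   levels = 8L)
  expect_identical(nrow(tab), 4L * 24L)    # 4 settings x 24 texture features
  expect_true(all(abs(tab$r) <= 1))
  one <- texture_sensitivity_sweep(d, windows = 5L, displacements = 1L,
                                   levels = 8L)
  expect_identical(unique(one$window), 5L)
  # the default grid evaluates all 5 x 3 = 15 settings
  cfg2 <- tiny_scene_config(n_points = 6L, patch_px = 12L, seed = 4L)
  d2 <- generate_time_series_dataset(cfg2)
  full_grid <- texture_sensitivity_sweep(d2, levels = 8L)
  expect_identical(nrow(unique(full_grid[c("window", "displacement")])), 15L)
  # the one geometrically empty setting (3x3 window, 3-pixel offset) is
  # reported with NA correlations rather than silently dropped
  empty <- full_grid[full_grid$window == 3 & full_grid$displacement == 3, ]
  expect_true(all(is.na(empty$r)))
  expect_true(all(!is.na(full_grid$r[full_grid$window > full_grid$displacement])))
})

test_that("contrast tracks LAI when texture amplitude is coupled to it", {
  cfg <- tiny_scene_config(n_points = 24L, texture_amp = 0.06, dn_noise = 0,
                           gain_range = c(1, 1), bias_range = c(0, 0),
                           seed = 8L)
  d <- generate_time_series_dataset(cfg)
  tab <- texture_sensitivity_sweep(d, windows = c(5L, 9L), displacements = 1:2,
                                   levels = 16L)
  con_g <- tab[tab$feature == "CON_G", ]
  expect_true(all(con_g$r > 0))
})
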