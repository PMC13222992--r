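test_that("response curve interpolates panel knots and clamps outside", {
  panel <- structure(list(R = data.frame(dn = c(0, 255), reflectance = c(0, 1)),
                          G = data.frame(dn = c(0, 255), reflectance = c(0, 1)),
                          B = data.frame(dn = c(0, 255), reflectance = c(0, 1))),
                     class = "panel_observations")
  curve <- fit_radiometric_response(panel)
  expect_equal(uavlai:::eval_response(curve, "R", 127.5), 0.5)
  expect_equal(uavlai:::eval_response(curve, "R", -10), 0)
  expect_equal(uavlai:::eval_response(curve, "R", 400), 1)

  cfg <- tiny_scene_config(gamma = 1)
  p <- generate_panel_observations(cfg, noise_sd = 0)
  c2 <- fit_radiometric_response(p)
  # exact at all 24 knots
  expect_equal(uavlai:::eval_response(c2, "G", p$G$dn), p$G$reflectance)
})

test_that("non-monotone panel pairs are rejected with the offending band", {
  panel <- structure(list(R = data.frame(dn = c(0, 100, 90),
                                         reflectance = c(0, .5, .9))),
                     class = "panel_observations")
  names(panel) <- "R"
  expect_error(fit_radiometric_response(panel), "band R.*step 3")
})

test_that("calibration round-trips the generator's reflectance field", {
  cfg <- tiny_scene_config(texture_amp = 0.04, dn_noise = 0,
                           gain_range = c(1, 1), bias_range = c(0, 0),
                           gamma = 0.5)
  # dense panel: piecewise-linear interpolation error vanishes with step
  panel <- generate_panel_observations(cfg, n_steps = 4001L, noise_sd = 0)
  curve <- fit_radiometric_response(panel)
  refl <- uavlai:::render_canopy_patch(4.4, cfg)
  dn <- uavlai:::reflectance_to_dn(refl, cfg)
  back <- apply_radiometric_calibration(dn, curve)
  expect_lt(max(abs(back - refl)), 1e-6)
  expect_identical(attr(back, "units"), "reflectance")
  # constant DN image stays constant
  const <- array(100, c(4, 4, 3))
  cal <- apply_radiometric_calibration(const, curve)
  expect_equal(length(unique(as.vector(cal))), 1L)
  # band-count mismatch
  expect_error(apply_radiometric_calibration(array(1, c(2, 2, 2)), curve),
               "band")
})

test_that("histogram matching removes gain/bias distortion", {
  set.seed(5)
  ref <- array(runif(32 * 32 * 3, 10, 200), c(32, 32, 3))
  img <- ref * 1.2 + 5
  matched <- histogram_match(img, ref)
  for (k in 1:3)
    expect_equal(mean(matched[, , k]), mean(ref[, , k]), tolerance = 0.01)
  # self-matching is (near) identity for float inputs
  self <- histogram_match(ref, ref)
  expect_equal(self, ref, tolerance = 1e-2)
  # idempotence
  twice <- histogram_match(matched, ref)
  expect_equal(twice, matched, tolerance = 1e-8)
  # constant reference collapses the output to that constant
  const <- array(7, c(32, 32, 3))
  expect_true(all(histogram_match(img, const) == 7))
  # 8-bit path: integer image matched to itself is identity
  int_img <- array(sample(0:255, 16 * 16 * 3, replace = TRUE), c(16, 16, 3))
  expect_equal(histogram_match(int_img, int_img), int_img)
  expect_error(histogram_match(array(1, c(2, 2, 3)), array(1, c(2, 2, 2))),
               "band count")
})

test_that("min-max normalization follows the fit/apply contract", {
  tab <- data.frame(a = c(2, 4, 6), b = c(5, 5, 5), lai = c(1, 2, 3))
  st <- fit_normalization(tab)
  out <- apply_normalization(tab, st)
  expect_equal(out$a, c(0, 0.5, 1))
  expect_equal(out$b, c(0, 0, 0))       # constant feature maps to 0
  expect_equal(out$lai, tab$lai)        # label column untouched
  # test values outside the training range are NOT clamped
  test <- data.frame(a = c(0, 8), b = c(5, 9), lai = c(1, 1))
  out2 <- apply_normalization(test, st)
  expect_equal(out2$a, c(-0.5, 1.5))
  expect_error(apply_normalization(data.frame(z = 1), st), "lacks feature")
})

test_that("missing timesteps are interpolated or the sample rejected", {
  F <- 4L
  mk <- function(present) {
    f <- matrix(rep(c(1, 2, 3), each = F), F, 3)
    f[, !present] <- NA
    structure(list(point_id = 1L, features = f, present = present,
                   lai = 4, patches = vector("list", 3)),
              class = "temporal_sample")
  }
  # interior gap: per-feature mean of neighbours
  s <- fill_missing_timesteps(mk(c(TRUE, FALSE, TRUE)))
  expect_equal(s$features[, 2], rep(2, F))
  expect_match(attr(s, "fill_log"), "interior")
  # edge gap: nearest present value
  s2 <- fill_missing_timesteps(mk(c(FALSE, TRUE, TRUE)))
  expect_equal(s2$features[, 1], s2$features[, 2])
  # two gaps: rejection with reason
  r <- fill_missing_timesteps(mk(c(FALSE, FALSE, TRUE)))
  expect_s3_class(r, "rejected_sample")
  expect_match(r$reason, "2 of 3")
  # complete sample unchanged
  s3 <- mk(c(TRUE, TRUE, TRUE))
  expect_identical(fill_missing_timesteps(s3), s3)
  # patch-mode interior gap
  p <- make_patch_samples(n = 1L, px = 6L)[[1]]
  p$present <- c(TRUE, FALSE, TRUE)
  filled <- p$patches[[2]]
  p$patches[2] <- list(NULL)
  pf <- fill_missing_timesteps(p)
  expect_equal(as.vector(pf$patches[[2]]),
               as.vector((pf$patches[[1]] + pf$patches[[3]]) / 2))
})
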