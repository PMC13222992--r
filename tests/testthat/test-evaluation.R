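dummy_samples <- function(n, per_point = 1L) {
  lapply(seq_len(n), function(i)
    structure(list(point_id = ((i - 1L) %/% per_point) + 1L,
                   lai = 4 + (i %% 7) / 10,
                   features = matrix(i + 0:5, 2, 3,
                                     dimnames = list(c("u", "v"), NULL)),
                   synthetic = FALSE,
                   parent_points = ((i - 1L) %/% per_point) + 1L),
              class = "temporal_sample"))
}

test_that("sample-level split counts round half up", {
  s <- dummy_samples(1632L)
  plan <- split_samples(s, 0.8, mode = "sample", seed = 1L)
  expect_length(plan$train_idx, 1306L)
  expect_length(plan$test_idx, 326L)
  s10 <- dummy_samples(10L)
  p10 <- split_samples(s10, 0.8, mode = "sample", seed = 2L)
  expect_length(p10$train_idx, 8L)
  expect_error(split_samples(s10, 1.2), "fraction")
})

test_that("point-level split keeps whole points together", {
  s <- dummy_samples(10L, per_point = 2L)       # 5 points x 2 samples
  plan <- split_samples(s, 0.8, mode = "point", seed = 3L)
  expect_length(plan$train_idx, 8L)
  expect_length(plan$train_points, 4L)
  expect_length(intersect(plan$train_points, plan$test_points), 0L)
  # determinism and the disjointness invariant across seeds
  for (sd in 1:20) {
    p <- split_samples(s, 0.8, mode = "point", seed = sd)
    expect_identical(p, split_samples(s, 0.8, mode = "point", seed = sd))
    expect_length(intersect(p$train_points, p$test_points), 0L)
  }
  one_pt <- dummy_samples(4L, per_point = 4L)
  expect_error(split_samples(one_pt, 0.8, mode = "point"), ">= 2 points")
})

test_that("k-fold partitions points evenly and reproducibly", {
  s <- dummy_samples(40L, per_point = 2L)       # 20 points
  folds <- kfold_by_point(s, k = 10L, seed = 4L)
  expect_length(folds, 10L)
  sizes <- vapply(folds, length, integer(1))
  expect_true(all(sizes == 4L))                 # 2 points x 2 samples
  expect_setequal(unlist(folds), seq_len(40L))
  expect_identical(sum(vapply(folds, length, integer(1))), 40L)
  # no point straddles folds
  pts <- vapply(s, `[[`, numeric(1), "point_id")
  for (f in folds) {
    others <- setdiff(unlist(folds), f)
    expect_length(intersect(pts[f], pts[others]), 0L)
  }
  expect_identical(folds, kfold_by_point(s, k = 10L, seed = 4L))
  expect_error(kfold_by_point(s, k = 25L), "exceeds")
})

test_that("regression metrics match hand values and the loop oracle", {
  y <- c(4, 5)
  m <- regression_metrics(y, y)
  expect_equal(m$r2, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$mae, 0)
  m2 <- regression_metrics(c(4, 5), c(5, 4))
  expect_equal(m2$rmse, 1)
  expect_equal(m2$mae, 1)
  expect_equal(m2$r2, -3)
  set.seed(8)
  yt <- runif(50, 3, 5)
  expect_equal(regression_metrics(yt, rep(mean(yt), 50))$r2, 0,
               tolerance = 1e-12)
  for (i in 1:10) {
    yp <- yt + rnorm(50, 0, 0.3)
    a <- regression_metrics(yt, yp)
    b <- oracle_metrics(yt, yp)
    for (k in names(b)) expect_equal(a[[k]], b[[k]], tolerance = 1e-12)
  }
  z <- regression_metrics(rep(4, 5), runif(5))
  expect_true(is.na(z$r2) && z$undefined_r2)
  expect_error(regression_metrics(1:3, 1:4), "length mismatch")
})

test_that("paired bootstrap p-values behave at the boundaries", {
  set.seed(9)
  r <- rnorm(100)
  expect_equal(paired_bootstrap_test(r, r, seed = 1L), 1)   # ties count as >=
  expect_equal(paired_bootstrap_test(rep(0, 100), rep(1, 100), seed = 1L), 0)
  expect_equal(paired_bootstrap_test(rep(1, 100), rep(0, 100), seed = 1L), 1)
  # planted 2x error ratio is detected
  a <- rnorm(200, 0, 1); b <- 2 * rnorm(200, 0, 1)
  expect_lt(paired_bootstrap_test(a, b, seed = 2L), 0.05)
  # invariant to common positive rescaling
  expect_identical(paired_bootstrap_test(a, b, seed = 3L),
                   paired_bootstrap_test(10 * a, 10 * b, seed = 3L))
  expect_error(paired_bootstrap_test(1:3, 1:4), "length")
})

test_that("repeated evaluation reports uncertainty and guards leakage", {
  s <- make_feature_samples(n = 50L, seed = 14L)
  split <- split_samples(s, mode = "point", seed = 5L)
  cfg <- model_config(knn_k = 3L, seed = 1L)
  rep <- repeated_evaluation(function(sd) build_baseline("knn", cfg),
                             s, split, n_repeats = 3L, seed = 7L)
  # knn is deterministic across repeats: SD 0 and zero-width CI
  expect_equal(rep$summary$sd[rep$summary$metric == "r2"], 0)
  expect_equal(diff(rep$r2_ci), 0)
  expect_true(rep$r2_ci[1] <= mean(rep$per_repeat$r2) &&
              mean(rep$per_repeat$r2) <= rep$r2_ci[2])
  # single repeat: SD undefined
  r1 <- repeated_evaluation(function(sd) build_baseline("knn", cfg),
                            s, split, n_repeats = 1L, seed = 8L)
  expect_false(r1$sd_defined)
  expect_true(all(is.na(r1$summary$sd)))
})

test_that("augmented samples may not cross the train/test boundary", {
  s <- make_patch_samples(n = 6L)
  split <- split_samples(s, 0.8, mode = "point", seed = 9L)
  train <- s[split$train_idx]
  aug <- augment_training_set(train, 4L, seed = 10L)
  expect_silent(uavlai:::assert_no_augmentation_leakage(aug, split))
  # forge a synthetic sample descending from a test point
  bad <- aug[[length(aug)]]
  bad$parent_points <- c(bad$parent_points[1], split$test_points[1])
  expect_error(uavlai:::assert_no_augmentation_leakage(c(aug, list(bad)),
                                                       split),
               "crosses the train/test boundary")
})

test_that("input size study reports the pixel-ratio scaling", {
  # ratio checks are arithmetic on the supported size list
  sizes <- c(16L, 32L, 64L, 96L, 128L, 192L, 224L)
  expect_equal((224 / 16)^2, 196)
  cfg <- tiny_scene_config(n_points = 20L, seed = 15L)
  d <- generate_time_series_dataset(cfg)
  split <- split_samples(d, mode = "point", seed = 11L)
  mc <- model_config(mode = "image", max_epochs = 12L, patience = 6L,
                     filters = c(8L, 12L, 16L), gru_units = c(16L, 8L),
                     branch_units = 8L, head_units = c(16L, 8L), seed = 3L)
  tab <- input_size_study(d, split, sizes = c(16L, 32L), config = mc,
                          n_repeats = 1L, seed = 12L)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$pixel_ratio, c(1, 4))
  expect_true(all(is.finite(tab$mean_r2)))
  expect_error(input_size_study(d, split, sizes = c(-3L), config = mc),
               "positive")
})
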