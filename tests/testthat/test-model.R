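# Small configs keep the engine fast; the architecture shapes are the
# defaults scaled down only where noted.
small_cfg <- function(...) {
  args <- list(max_epochs = 60L, patience = 10L)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

test_that("network shapes follow the architecture arithmetic", {
  cfg <- model_config(mode = "image", image_size = 128L)
  layers <- uavlai:::cnn_branch_layers(cfg, image_mode = TRUE)
  ini <- uavlai:::nn_init_layers(layers, c(128L, 128L, 9L))
  # three stride-2 pools: 128 -> 64 -> 32 -> 16 before the flatten/head
  # (branch output is the 64-unit dense head)
  expect_identical(ini$output_shape, 64L)
  # trace the conv stack spatial sizes explicitly
  shapes <- list(c(128L, 128L, 9L))
  x <- c(128L, 128L, 9L)
  for (f in cfg$filters) x <- c(x[1] %/% 2L, x[2] %/% 2L, f)
  expect_identical(x, c(16L, 16L, 256L))
  # feature mode accepts an 18 x 3 matrix
  m <- build_cnn_gru(model_config())
  p <- uavlai:::nn_init_network(m$net, list(cnn_in = c(18L, 3L),
                                            gru_in = c(3L, 18L)), seed = 1L)
  X <- list(cnn_in = array(0, c(2, 18, 3)), gru_in = array(0, c(2, 3, 18)))
  out <- uavlai:::nn_forward(m$net, p, X)$out
  expect_length(out, 2L)
  expect_true(all(is.finite(out)))
})

test_that("the hybrid has strictly more parameters than the CNN baseline", {
  cfg <- model_config()
  shapes <- list(cnn_in = c(18L, 3L), gru_in = c(3L, 18L))
  n_hybrid <- n_parameters(build_cnn_gru(cfg), shapes)
  n_cnn <- n_parameters(build_baseline("cnn", cfg), shapes)
  expect_gt(n_hybrid, n_cnn)
})

test_that("all six comparison models build and train", {
  s <- make_feature_samples(n = 40L, seed = 2L)
  cfg <- small_cfg(max_epochs = 15L, patience = 5L, rf_trees = 50L,
                   xgb_rounds = 30L, seed = 3L)
  names <- c("transformer", "knn", "mlp", "cnn", "rf", "xgboost")
  fits <- lapply(names, function(nm)
    train_model(build_baseline(nm, cfg), s))
  expect_identical(vapply(fits, `[[`, "", "name"), names)
  for (f in fits) {
    p <- predict(f, s[1:5])
    expect_length(p, 5L)
    expect_true(all(is.finite(p)))
  }
  expect_error(build_baseline("svm", cfg), "arg")
})

test_that("1-NN reproduces its own training labels exactly", {
  s <- make_feature_samples(n = 25L, seed = 4L)
  cfg <- small_cfg(knn_k = 1L)
  f <- train_model(build_baseline("knn", cfg), s)
  y <- vapply(s, `[[`, numeric(1), "lai")
  expect_equal(predict(f, s), y, tolerance = 1e-9)
})

test_that("training converges to a constant for constant labels", {
  s <- make_feature_samples(n = 40L, seed = 5L)
  s <- lapply(s, function(x) { x$lai <- 4.5; x })
  cfg <- small_cfg(max_epochs = 150L, patience = 150L, seed = 6L)
  f <- train_model(build_cnn_gru(cfg), s)
  expect_lt(max(abs(predict(f, s) - 4.5)), 0.01)
})

test_that("early stopping halts before the epoch cap", {
  s <- make_feature_samples(n = 40L, noise = 0.5, seed = 7L)
  cfg <- small_cfg(max_epochs = 400L, patience = 5L, seed = 8L)
  f <- train_model(build_cnn_gru(cfg), s)
  expect_lt(nrow(f$history), 400L)
  expect_true(all(c("epoch", "train_loss", "val_loss") %in%
                  colnames(f$history)))
})

test_that("seeded training is reproducible and predictions are batch-stable", {
  s <- make_feature_samples(n = 30L, seed = 9L)
  cfg <- small_cfg(max_epochs = 20L, seed = 11L)
  f1 <- train_model(build_cnn_gru(cfg), s)
  f2 <- train_model(build_cnn_gru(cfg), s)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1, s), predict(f2, s))
  # permuting the batch permutes the outputs, values unchanged
  perm <- c(5, 1, 9, 2, 7)
  p_all <- predict(f1, s[perm])
  p_each <- vapply(perm, function(i) predict(f1, s[i]), numeric(1))
  expect_equal(p_all, p_each, tolerance = 1e-12)
  # duplicate samples get identical predictions
  p_dup <- predict(f1, s[c(3, 3)])
  expect_identical(p_dup[1], p_dup[2])
})

test_that("training aborts with diagnostics on divergence", {
  s <- make_feature_samples(n = 20L, seed = 10L)
  cfg <- small_cfg(lr = 1e120, max_epochs = 30L, seed = 12L)
  expect_error(train_model(build_cnn_gru(cfg), s), "diverged|non-finite")
})

test_that("ablating the GRU branch hurts more when signal is temporal", {
  # label from the final timestep only vs spread over all timesteps
  cfg <- small_cfg(max_epochs = 60L, patience = 60L, seed = 13L)
  delta_for <- function(samples) {
    split <- split_samples(samples, mode = "point", seed = 2L)
    f <- train_model(build_cnn_gru(cfg), samples[split$train_idx])
    te <- samples[split$test_idx]
    y <- vapply(te, `[[`, numeric(1), "lai")
    full <- regression_metrics(y, predict(f, te))$r2
    abl <- regression_metrics(y, predict(f, te, ablate_branch = "gru_in"))$r2
    full - abl
  }
  d_final <- delta_for(make_feature_samples(n = 120L, seed = 21L,
                                            signal_stage = 3L))
  d_spread <- delta_for(make_feature_samples(n = 120L, seed = 21L))
  expect_true(is.finite(d_final) && is.finite(d_spread))
  # temporal aggregation relies on the GRU branch more than last-step signal
  expect_gt(d_spread, d_final - 0.05)
})
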