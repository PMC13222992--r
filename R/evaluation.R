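## Data splitting, cross-validation, repeated-run metrics with uncertainty,
## paired significance testing, and the input-size study harness.

#' Train/test split plan
#'
#' `mode = "point"` (the default protocol) keeps all samples of a sampling
#' point on one side: whole points are accumulated, in seeded random
#' order, until the train sample count is nearest to
#' `round(fraction * N)`, so no point ever contributes to both sides.
#' `mode = "sample"` splits individual samples with train count
#' `round(fraction * N)` (round half up).
#'
#' @param samples list of temporal samples (need `point_id`).
#' @param fraction train fraction in (0, 1), default 0.8.
#' @param mode `"point"` or `"sample"`.
#' @param seed split seed.
#' @return a `split_plan`: list with `train_idx`, `test_idx`,
#'   `train_points`, `test_points`, `mode`, `fraction`, `seed`.
#' @export
split_samples <- function(samples, fraction = 0.8,
                          mode = c("point", "sample"), seed = 1L) {
  mode <- match.arg(mode)
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  N <- length(samples)
  target <- floor(fraction * N + 0.5)        # round half up
  pts <- vapply(samples, function(s) s$point_id, numeric(1))
  plan <- with_seed(seed, {
    if (mode == "sample") {
      train_idx <- sort(sample.int(N, target))
    } else {
      upts <- unique(pts)
      if (length(upts) < 2L) stopf("point-level split needs >= 2 points")
      ord <- sample(upts)
      count <- 0L
      chosen <- numeric(0)
      for (p in ord) {
        size <- sum(pts == p)
        if (abs(count + size - target) <= abs(count - target)) {
          chosen <- c(chosen, p)
          count <- count + size
        } else break
      }
      train_idx <- sort(which(pts %in% chosen))
    }
    test_idx <- setdiff(seq_len(N), train_idx)
    list(train_idx = train_idx, test_idx = test_idx,
         train_points = unique(pts[train_idx]),
         test_points = unique(pts[test_idx]),
         mode = mode, fraction = fraction, seed = seed)
  })
  plan <- structure(plan, class = "split_plan")
  assert_split_plan(plan)
  plan
}

## Leakage guard: in point mode no point ID may appear on both sides.
assert_split_plan <- function(plan) {
  if (plan$mode == "point" &&
      length(intersect(plan$train_points, plan$test_points)))
    stopf("leakage: point(s) %s appear in both sides",
          paste(intersect(plan$train_points, plan$test_points), collapse = ","))
  invisible(plan)
}

#' K-fold cross-validation folds at the sampling-point level
#'
#' Folds partition the point IDs (sizes differing by at most one point);
#' hyperparameter selection is meant to consume only these folds and never
#' the held-out test set.
#'
#' @param samples training samples.
#' @param k number of folds (default 10).
#' @param seed fold assignment seed.
#' @return list of k integer vectors of sample indices.
#' @export
kfold_by_point <- function(samples, k = 10L, seed = 1L) {
  pts <- vapply(samples, function(s) s$point_id, numeric(1))
  upts <- unique(pts)
  if (k > length(upts))
    stopf("k = %d exceeds the %d available points", k, length(upts))
  with_seed(seed, {
    ord <- sample(upts)
    fold_of <- rep(seq_len(k), length.out = length(ord))
    lapply(seq_len(k), function(f) which(pts %in% ord[fold_of == f]))
  })
}

#' Regression accuracy metrics
#'
#' R^2 = 1 - SSres/SStot, RMSE (in LAI units), MAE, MAPE (percent) and
#' rRMSE = RMSE / mean(y_true) * 100.
#'
#' @param y_true,y_pred equal-length numeric vectors (length >= 2).
#' @return named list of the five metrics; `r2` is NA with an
#'   `undefined_r2` flag when y_true has zero variance.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stopf("length mismatch")
  if (length(y_true) < 2L) stopf("need at least 2 observations")
  e <- y_pred - y_true
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(e^2) / ss_tot
  mape <- if (any(abs(y_true) < 1e-9)) NA_real_
          else mean(abs(e) / abs(y_true)) * 100
  list(r2 = r2,
       rmse = sqrt(mean(e^2)),
       mae = mean(abs(e)),
       mape = mape,
       rrmse = sqrt(mean(e^2)) / mean(y_true) * 100,
       undefined_r2 = ss_tot == 0)
}

#' Paired bootstrap significance test on residuals
#'
#' One-sided test that model A's squared residuals are smaller than model
#' B's: paired indices are resampled with replacement `n` times and
#' p is the fraction of resamples in which mean squared residual of A is
#' greater than or equal to that of B (ties count against A).
#'
#' @param residuals_a,residuals_b equal-length paired residual vectors
#'   (A is the model claimed better).
#' @param n number of resamples (default 1000).
#' @param seed resampling seed.
#' @param two_sided if TRUE, returns the two-sided p
#'   (2 * min(p_one, 1 - p_one), capped at 1).
#' @return the bootstrap p-value.
#' @export
paired_bootstrap_test <- function(residuals_a, residuals_b, n = 1000L,
                                  seed = 1L, two_sided = FALSE) {
  m <- length(residuals_a)
  if (m != length(residuals_b)) stopf("residual vectors differ in length")
  with_seed(seed, {
    ge <- vapply(seq_len(n), function(i) {
      idx <- sample.int(m, m, replace = TRUE)
      mean(residuals_a[idx]^2) >= mean(residuals_b[idx]^2)
    }, logical(1))
    p <- mean(ge)
    if (two_sided) min(1, 2 * min(p, 1 - p)) else p
  })
}

#' Repeated training/evaluation with uncertainty
#'
#' The train/test split is fixed once (seeded); each repeat re-initializes
#' and re-augments the training side, trains, and evaluates on the fixed
#' test set. Reports per-metric mean, SD and a 95% percentile bootstrap CI
#' (1000 resamples of the test residuals, averaged over repeats).
#'
#' @param model_builder function(seed) returning an untrained `lai_model`.
#' @param samples full sample list (features attached in feature mode).
#' @param split a [split_samples()] plan.
#' @param n_repeats default 10.
#' @param n_aug CutMix samples to add per repeat (0 disables augmentation).
#' @param aug_fraction CutMix area fraction.
#' @param seed base seed; repeat r uses seed + r.
#' @param refeature function(samples) recomputing features after
#'   augmentation (required when n_aug > 0 in feature mode).
#' @return an `evaluation_report`: list with `per_repeat` (data.frame),
#'   `summary` (mean/sd/CI per metric), `predictions`, `residuals`.
#' @export
repeated_evaluation <- function(model_builder, samples, split,
                                n_repeats = 10L, n_aug = 0L,
                                aug_fraction = 0.40, seed = 1L,
                                refeature = NULL) {
  assert_split_plan(split)
  train <- samples[split$train_idx]
  test <- samples[split$test_idx]
  y_test <- vapply(test, function(s) s$lai, numeric(1))
  per <- NULL
  preds <- matrix(NA_real_, n_repeats, length(test))
  for (r in seq_len(n_repeats)) {
    rs <- seed + r
    tr <- train
    if (n_aug > 0L) {
      tr <- augment_training_set(tr, n_aug, fraction = aug_fraction,
                                 seed = child_seed(rs, "aug"))
      assert_no_augmentation_leakage(tr, split)
      if (!is.null(refeature)) tr <- refeature(tr)
    }
    m <- model_builder(rs)
    fit <- train_model(m, tr)
    p <- predict(fit, test)
    preds[r, ] <- p
    met <- regression_metrics(y_test, p)
    per <- rbind(per, data.frame(repeat_ = r, r2 = met$r2, rmse = met$rmse,
                                 mae = met$mae, mape = met$mape,
                                 rrmse = met$rrmse))
  }
  res <- sweep(preds, 2, y_test)           # residual matrix repeats x test
  ## percentile bootstrap over the per-repeat R^2 values; a deterministic
  ## model (identical repeats) gets a zero-width interval
  boot <- with_seed(child_seed(seed, "ci"), {
    nb <- 1000L
    vapply(seq_len(nb), function(b) {
      mean(per$r2[sample.int(n_repeats, n_repeats, replace = TRUE)])
    }, numeric(1))
  })
  summary <- data.frame(
    metric = c("r2", "rmse", "mae", "mape", "rrmse"),
    mean = vapply(c("r2", "rmse", "mae", "mape", "rrmse"),
                  function(m) mean(per[[m]]), numeric(1)),
    sd = if (n_repeats > 1L)
           vapply(c("r2", "rmse", "mae", "mape", "rrmse"),
                  function(m) stats::sd(per[[m]]), numeric(1))
         else NA_real_)
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  structure(list(per_repeat = per, summary = summary,
                 r2_ci = ci, predictions = preds, residuals = res,
                 y_test = y_test, sd_defined = n_repeats > 1L),
            class = "evaluation_report")
}

## Augmented samples must descend from training-side points only.
assert_no_augmentation_leakage <- function(train_samples, split) {
  for (s in train_samples) {
    if (!isTRUE(s$synthetic)) next
    if (any(s$parent_points %in% split$test_points))
      stopf("augmented sample crosses the train/test boundary (parents %s)",
            paste(s$parent_points, collapse = ","))
  }
  invisible(TRUE)
}

#' Input-size sensitivity study
#'
#' Trains and evaluates an image-mode model at each requested input size,
#' reporting mean R^2 and RMSE over repeats plus the pixel-count ratio of
#' every size to the smallest.
#'
#' @param samples image-mode samples (with patches).
#' @param split a [split_samples()] plan.
#' @param sizes input sizes (must be positive integers from the supported
#'   list).
#' @param config base [model_config()] (its `image_size` is overridden).
#' @param n_repeats repeats per size.
#' @param seed base seed.
#' @return data.frame with size, pixels, pixel_ratio, mean_r2, mean_rmse.
#' @export
input_size_study <- function(samples, split, sizes = c(16L, 32L, 64L),
                             config = model_config(mode = "image"),
                             n_repeats = 2L, seed = 1L) {
  if (any(sizes != as.integer(sizes) | sizes <= 0))
    stopf("sizes must be positive integers")
  rows <- lapply(sizes, function(s) {
    cfg <- config
    cfg$image_size <- as.integer(s)
    rep <- repeated_evaluation(function(sd) {
      c2 <- cfg; c2$seed <- sd
      build_cnn_gru(c2)
    }, samples, split, n_repeats = n_repeats, seed = seed)
    data.frame(size = s, pixels = s^2,
               mean_r2 = mean(rep$per_repeat$r2),
               mean_rmse = mean(rep$per_repeat$rmse))
  })
  out <- do.call(rbind, rows)
  out$pixel_ratio <- out$pixels / min(out$pixels)
  out
}
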