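## End-to-end pipeline: calibrate -> normalize dates -> features -> screen
## -> split -> CutMix-augment -> train CNN-GRU -> evaluate.

#' Calibrate and cross-date normalize a sample set
#'
#' Applies the fitted radiometric response to every patch (DN ->
#' reflectance), then removes residual per-date illumination differences by
#' matching each date's pooled pixel distribution (over all patches of that
#' date) to the reference date's, per band.
#'
#' @param samples list of temporal samples with DN patches.
#' @param curve a [fit_radiometric_response()] result.
#' @param reference_date date index whose distribution the others are
#'   matched to (default 1, the first flight).
#' @param match_dates set FALSE to skip histogram matching.
#' @return samples with reflectance patches.
#' @export
calibrate_samples <- function(samples, curve, reference_date = 1L,
                              match_dates = TRUE) {
  samples <- lapply(samples, function(s) {
    s$patches <- lapply(s$patches, function(p) {
      if (is.null(p)) return(NULL)
      apply_radiometric_calibration(p, curve)
    })
    s
  })
  if (!match_dates) return(samples)
  L <- max(vapply(samples, function(s) length(s$patches), integer(1)))
  ## pooled per-date, per-band quantile mapping to the reference date
  pool <- function(t, k) {
    unlist(lapply(samples, function(s) {
      p <- s$patches[[t]]
      if (is.null(p)) NULL else as.vector(p[, , k])
    }), use.names = FALSE)
  }
  for (t in setdiff(seq_len(L), reference_date)) {
    for (k in 1:3) {
      src <- pool(t, k)
      if (!length(src)) next
      ref <- pool(reference_date, k)
      n <- length(src)
      pr <- (rank(src, ties.method = "average") - 0.5) / n
      mapped <- stats::quantile(ref, probs = pr, names = FALSE, type = 7)
      ## scatter the mapped values back into the patches
      off <- 0L
      for (i in seq_along(samples)) {
        p <- samples[[i]]$patches[[t]]
        if (is.null(p)) next
        m <- length(p[, , k])
        samples[[i]]$patches[[t]][, , k] <- mapped[off + seq_len(m)]
        off <- off + m
      }
    }
  }
  samples
}

#' Build a feature table from temporal samples
#'
#' One row per (point, stage): point ID, stage index, the stage's LAI (from
#' the sample's trajectory when available, otherwise the label) and the
#' extracted features of the stage patch. This is the table the screening
#' module consumes.
#'
#' @param samples samples with `$features` matrices (see
#'   [attach_sample_features()]).
#' @return data.frame with columns point_id, stage, lai and one column per
#'   feature.
#' @export
build_feature_table <- function(samples) {
  rows <- list()
  for (s in samples) {
    L <- ncol(s$features)
    for (t in seq_len(L)) {
      if (any(is.na(s$features[, t]))) next
      lai_t <- if (!is.null(s$lai_trajectory)) s$lai_trajectory[t] else s$lai
      rows[[length(rows) + 1L]] <- c(point_id = s$point_id, stage = t,
                                     lai = lai_t, s$features[, t])
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  out
}

#' Run the full LAI inversion pipeline on synthetic data
#'
#' Generates a seeded synthetic benchmark, calibrates it against its own
#' panel, normalizes dates, extracts all candidate features, screens them
#' (Pearson then VIF), splits at the sampling-point level, optionally
#' CutMix-augments the training side (features recomputed from mixed
#' patches), trains the parallel CNN-GRU on the retained feature matrices
#' and evaluates on the held-out points.
#'
#' @param config a [scene_config()] (defaults: 300 points, L = 3).
#' @param model_cfg a [model_config()]; its seed drives training.
#' @param feature_cfg a [feature_config()] for extraction.
#' @param augment add CutMix samples to the training set.
#' @param n_aug number of CutMix samples (default: one per training
#'   sample, doubling the training set).
#' @param split_seed seed of the fixed point-level 80/20 split.
#' @return list with `metrics` (held-out [regression_metrics()]),
#'   `screening` (report), `retained`, `split`, `trained`, `predictions`,
#'   `y_test`, `n_train`, `n_test`.
#' @export
run_lai_pipeline <- function(config = scene_config(n_points = 300L),
                             model_cfg = model_config(max_epochs = 150L,
                                                      patience = 15L),
                             feature_cfg = feature_config(),
                             augment = TRUE, n_aug = NULL,
                             split_seed = 1L) {
  samples <- generate_time_series_dataset(config)
  panel <- generate_panel_observations(config)
  curve <- fit_radiometric_response(panel)
  samples <- calibrate_samples(samples, curve)
  ## missing-timestep handling: interpolate single gaps, drop the rest
  kept <- list()
  for (s in samples) {
    r <- fill_missing_timesteps(s)
    if (!inherits(r, "rejected_sample")) kept[[length(kept) + 1L]] <- r
  }
  samples <- attach_sample_features(kept, feature_cfg)
  table <- build_feature_table(samples)
  screening <- screen_features(table)
  retained <- attr(screening, "retained")
  split <- split_samples(samples, fraction = 0.8, mode = "point",
                         seed = split_seed)
  train <- samples[split$train_idx]
  test <- samples[split$test_idx]
  if (augment) {
    if (is.null(n_aug)) n_aug <- length(train)
    train <- augment_training_set(train, n_aug,
                                  seed = child_seed(model_cfg$seed, "aug"))
    assert_no_augmentation_leakage(train, split)
    ## synthetic samples need their features recomputed from mixed patches
    idx <- which(vapply(train, function(s) isTRUE(s$synthetic), logical(1)))
    train[idx] <- attach_sample_features(train[idx], feature_cfg)
  }
  subset_features <- function(ss) lapply(ss, function(s) {
    s$features <- s$features[retained, , drop = FALSE]
    s
  })
  trained <- train_model(build_cnn_gru(model_cfg), subset_features(train))
  pred <- predict(trained, subset_features(test))
  y_test <- vapply(test, function(s) s$lai, numeric(1))
  list(metrics = regression_metrics(y_test, pred), screening = screening,
       retained = retained, split = split, trained = trained,
       predictions = pred, y_test = y_test,
       n_train = length(train), n_test = length(test),
       samples = samples, feature_cfg = feature_cfg)
}
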