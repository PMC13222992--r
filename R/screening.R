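## Two-step feature optimization: per-stage Pearson screening, iterative
## VIF elimination, and partial-correlation verification of the retained set.

#' Per-feature, per-stage Pearson correlation with LAI
#'
#' @param table data.frame with feature columns plus `stage` and `lai`.
#' @return matrix (features x stages) of Pearson r; constant feature
#'   columns get r = 0 and are listed in the `"degenerate"` attribute.
#' @export
pearson_by_stage <- function(table) {
  feats <- feature_columns(table)
  stages <- unique(table$stage)
  counts <- table(table$stage)
  if (any(counts < 3L))
    stopf("every stage needs >= 3 samples (smallest has %d)", min(counts))
  degenerate <- character(0)
  r <- sapply(stages, function(st) {
    rows <- table$stage == st
    lai <- table$lai[rows]
    vapply(feats, function(f) {
      x <- table[[f]][rows]
      if (stats::sd(x) == 0 || stats::sd(lai) == 0) {
        degenerate <<- union(degenerate, f)
        0
      } else stats::cor(x, lai)
    }, numeric(1))
  })
  r <- matrix(r, nrow = length(feats), dimnames = list(feats, stages))
  attr(r, "degenerate") <- degenerate
  r
}

#' Correlation screening across stages
#'
#' A feature is eliminated only when its |r| with LAI is strictly below the
#' threshold in every stage; a feature reaching the threshold in at least
#' one stage is retained (|r| exactly at the threshold is retained).
#'
#' @param r matrix from [pearson_by_stage()].
#' @param threshold default 0.10.
#' @return character vector of retained feature names.
#' @export
screen_by_correlation <- function(r, threshold = 0.10) {
  keep <- apply(abs(r) >= threshold, 1, any)
  rownames(r)[keep]
}

#' Variance inflation factor of one feature against its co-features
#'
#' VIF = 1 / (1 - R^2) of the least-squares regression (with intercept) of
#' the feature on all other feature columns. Perfect collinearity returns
#' `Inf`.
#'
#' @param table data.frame of candidate features (bookkeeping columns are
#'   ignored).
#' @param feature name of the feature to assess.
#' @return the VIF, a number >= 1 or `Inf`.
#' @export
compute_vif <- function(table, feature) {
  feats <- feature_columns(table)
  if (!(feature %in% feats)) stopf("unknown feature '%s'", feature)
  others <- setdiff(feats, feature)
  if (length(others) < 1L) stopf("need at least 2 features for a VIF")
  n <- nrow(table)
  if (n <= length(others) + 1L)
    stopf("rank deficiency: n = %d rows but %d predictors", n, length(others))
  y <- table[[feature]]
  X <- cbind(1, as.matrix(table[others]))
  fit <- stats::lm.fit(X, y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(Inf)
  r2 <- 1 - ss_res / ss_tot
  if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
}

#' Iterative VIF elimination
#'
#' Repeatedly removes the single feature with the highest VIF strictly
#' above the threshold (a VIF exactly at the threshold is retained),
#' recomputing after each removal. Ties are broken by earliest column
#' order for reproducibility.
#'
#' @param table data.frame of correlation-screened candidate features.
#' @param threshold default 10.
#' @return list with `retained` (names) and `trace` (data.frame of removed
#'   feature, its VIF, and removal order).
#' @export
screen_by_vif <- function(table, threshold = 10) {
  feats <- feature_columns(table)
  trace <- data.frame(feature = character(0), vif = numeric(0),
                      order = integer(0))
  repeat {
    if (length(feats) < 2L) break
    sub <- table[feats]
    vifs <- vapply(feats, function(f) compute_vif(sub, f), numeric(1))
    worst <- max(vifs)
    if (worst <= threshold) break
    drop <- feats[which(vifs == worst)[1]]   # earliest column on ties
    trace <- rbind(trace, data.frame(feature = drop, vif = worst,
                                     order = nrow(trace) + 1L))
    feats <- setdiff(feats, drop)
  }
  list(retained = feats, trace = trace)
}

#' Partial correlation between a feature and LAI given controls
#'
#' Pearson correlation between the residuals of (feature ~ controls) and
#' (LAI ~ controls), both residualized by least squares with intercept.
#' A feature fully explained by the controls has zero residual variance
#' and returns 0 with a `"degenerate"` attribute.
#'
#' @param table data.frame with the feature, the controls and `lai`.
#' @param feature feature name.
#' @param controls character vector of control feature names (may be empty,
#'   in which case the plain Pearson r is returned).
#' @return the partial correlation coefficient.
#' @export
partial_correlation <- function(table, feature, controls = character(0)) {
  if (feature %in% controls) controls <- setdiff(controls, feature)
  y <- table$lai
  x <- table[[feature]]
  if (length(controls) == 0L) {
    if (stats::sd(x) == 0) return(structure(0, degenerate = TRUE))
    return(stats::cor(x, y))
  }
  Z <- cbind(1, as.matrix(table[controls]))
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stopf("rank-deficient control set")
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  ## residual variance at floating-point noise level means the feature is
  ## fully explained by the controls
  tol_x <- 1e-10 * (stats::sd(x) + 1e-300)
  tol_y <- 1e-10 * (stats::sd(y) + 1e-300)
  if (stats::sd(rx) <= tol_x || stats::sd(ry) <= tol_y)
    return(structure(0, degenerate = TRUE))
  stats::cor(rx, ry)
}

#' Full two-step feature screening with verification
#'
#' Runs the per-stage correlation screen, then iterative VIF elimination on
#' the survivors, then partial-correlation verification of every retained
#' feature (controlling for the other retained features).
#'
#' @param table feature table (one row per (point, stage), columns =
#'   features + point_id, stage, lai).
#' @param r_threshold correlation threshold (default 0.10).
#' @param vif_threshold VIF threshold (default 10).
#' @return a `screening_report`: data.frame with per-stage r, max |r|,
#'   VIF at elimination time (NA if never eliminated by VIF), partial r
#'   (retained features only), retained flag and elimination reason.
#' @export
screen_features <- function(table, r_threshold = 0.10, vif_threshold = 10) {
  r <- pearson_by_stage(table)
  feats <- rownames(r)
  keep_r <- screen_by_correlation(r, r_threshold)
  vif_res <- screen_by_vif(table[c(keep_r, "lai")], vif_threshold)
  retained <- vif_res$retained
  partial <- stats::setNames(rep(NA_real_, length(feats)), feats)
  for (f in retained)
    partial[f] <- partial_correlation(table, f, setdiff(retained, f))
  reason <- stats::setNames(rep(NA_character_, length(feats)), feats)
  reason[setdiff(feats, keep_r)] <-
    sprintf("|r| < %.2f in all stages", r_threshold)
  if (nrow(vif_res$trace))
    reason[vif_res$trace$feature] <-
      sprintf("VIF %.1f > %.0f", vif_res$trace$vif, vif_threshold)
  rep <- data.frame(feature = feats,
                    max_abs_r = apply(abs(r), 1, max),
                    vif_at_elimination = NA_real_,
                    partial_r = unname(partial),
                    retained = feats %in% retained,
                    reason = unname(reason),
                    row.names = NULL)
  if (nrow(vif_res$trace))
    rep$vif_at_elimination[match(vif_res$trace$feature, feats)] <- vif_res$trace$vif
  out <- cbind(rep, as.data.frame(r))
  structure(out, class = c("screening_report", "data.frame"),
            stage_r = r, vif_trace = vif_res$trace, retained = retained)
}
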