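## Radiometric calibration from panel observations, cross-date histogram
## matching, min-max feature normalization, and missing-timestep handling.

#' Fit a radiometric response curve from panel observations
#'
#' The camera's DN-to-reflectance response is modelled per band as a
#' monotone piecewise-linear curve through the panel knots. Outside the
#' fitted DN domain the curve clamps to the end reflectances. Piecewise
#' linearity guarantees monotonicity and exactness at the knots with no
#' polynomial oscillation.
#'
#' @param panel a `panel_observations` object (per band, ordered
#'   (DN, reflectance) pairs).
#' @return a `response_curve`: per-band knot tables plus the fit domain.
#' @export
fit_radiometric_response <- function(panel) {
  if (!inherits(panel, "panel_observations") && !is.list(panel))
    stopf("panel must be a panel_observations object")
  bands <- lapply(names(panel), function(b) {
    tab <- panel[[b]]
    if (nrow(tab) < 2L) stopf("band %s: need at least 2 panel steps", b)
    if (any(diff(tab$dn) <= 0)) {
      bad <- which(diff(tab$dn) <= 0)[1] + 1L
      stopf("band %s: DN values not strictly increasing at step %d", b, bad)
    }
    if (any(diff(tab$reflectance) <= 0)) {
      bad <- which(diff(tab$reflectance) <= 0)[1] + 1L
      stopf("band %s: reflectance not strictly increasing at step %d", b, bad)
    }
    if (any(tab$reflectance < 0 | tab$reflectance > 1))
      stopf("band %s: reflectance outside [0, 1]", b)
    tab
  })
  names(bands) <- names(panel)
  structure(list(bands = bands,
                 domain = lapply(bands, function(t) range(t$dn))),
            class = "response_curve")
}

## Evaluate one band of a response curve at DN values (vectorised).
eval_response <- function(curve, band, dn) {
  tab <- curve$bands[[band]]
  if (is.null(tab)) stopf("response curve has no band '%s'", band)
  out <- stats::approx(tab$dn, tab$reflectance, xout = dn, rule = 2)$y
  pmin(pmax(out, 0), 1)
}

#' Apply radiometric calibration to an image
#'
#' Converts a DN-unit RGB patch to relative reflectance by applying the
#' fitted per-band response curve pixelwise.
#'
#' @param image an `rgb_patch` (or plain H x W x 3 array) in DN units.
#' @param curve a [fit_radiometric_response()] result with bands R, G, B.
#' @return the calibrated patch, flagged `units = "reflectance"`.
#' @export
apply_radiometric_calibration <- function(image, curve) {
  if (!inherits(curve, "response_curve")) stopf("curve must be a response_curve")
  d <- dim(image)
  if (length(d) != 3L || d[3] != length(curve$bands))
    stopf("image has %d band(s) but the curve has %d",
          if (length(d) == 3L) d[3] else 1L, length(curve$bands))
  out <- image
  for (k in seq_len(d[3]))
    out[, , k] <- eval_response(curve, names(curve$bands)[k], image[, , k])
  attr(out, "units") <- "reflectance"
  out
}

#' Histogram matching against a reference image
#'
#' Per-band monotone CDF mapping: each band of `image` is remapped so its
#' empirical distribution matches the reference band. Used as relative
#' radiometric normalization across acquisition dates, with the first
#' date's image as the reference. Integer 8-bit inputs use a 256-bin CDF;
#' float inputs use exact quantile mapping.
#'
#' @param image,reference arrays with the same number of bands.
#' @return the matched image, same shape as `image`.
#' @export
histogram_match <- function(image, reference) {
  d <- dim(image); dr <- dim(reference)
  if (length(image) == 0L) stopf("empty image")
  nb <- if (length(d) == 3L) d[3] else 1L
  nbr <- if (length(dr) == 3L) dr[3] else 1L
  if (nb != nbr) stopf("band count mismatch: %d vs %d", nb, nbr)
  out <- image
  get_band <- function(x, k) if (length(dim(x)) == 3L) x[, , k] else x
  eightbit <- function(x) all(x == round(x)) && min(x) >= 0 && max(x) <= 255
  for (k in seq_len(nb)) {
    src <- get_band(image, k); ref <- get_band(reference, k)
    if (eightbit(src) && eightbit(ref)) {
      ## 256-bin empirical CDFs; map each level to the smallest reference
      ## level whose CDF reaches the source CDF
      cs <- cumsum(tabulate(src + 1L, 256L)) / length(src)
      cr <- cumsum(tabulate(ref + 1L, 256L)) / length(ref)
      lut <- vapply(cs, function(p) which(cr >= p - 1e-12)[1] - 1L, integer(1))
      mapped <- lut[src + 1L]
    } else {
      ## exact quantile mapping: x -> Q_ref(F_src(x))
      n <- length(src)
      r <- rank(src, ties.method = "average")
      p <- (r - 0.5) / n
      mapped <- stats::quantile(ref, probs = p, names = FALSE, type = 7)
    }
    if (length(dim(out)) == 3L) out[, , k] <- mapped else out <- mapped
  }
  out
}

#' Fit min-max normalization statistics
#'
#' Per-feature min and max, to be fit on training rows only (the evaluation
#' protocol asserts this). Applying the stats to the data they were fit on
#' maps every non-constant column onto `[0, 1]`.
#'
#' @param table data.frame or matrix of feature columns (non-numeric and
#'   bookkeeping columns `point_id`, `stage`, `lai` are ignored).
#' @return a `normalization_stats` object.
#' @export
fit_normalization <- function(table) {
  cols <- feature_columns(table)
  mins <- vapply(cols, function(c) min(table[[c]]), numeric(1))
  maxs <- vapply(cols, function(c) max(table[[c]]), numeric(1))
  structure(list(features = cols, min = mins, max = maxs),
            class = "normalization_stats")
}

feature_columns <- function(table) {
  nm <- colnames(table)
  keep <- setdiff(nm, c("point_id", "stage", "lai", "date", "synthetic"))
  keep[vapply(keep, function(c) is.numeric(table[[c]]), logical(1))]
}

#' Apply min-max normalization
#'
#' Values are scaled with the stored training min/max; constant training
#' features map to 0, and test values outside the training range are left
#' outside `[0, 1]` rather than clamped, preserving out-of-range signal.
#'
#' @param table data.frame with the features named in `stats`.
#' @param stats a [fit_normalization()] result.
#' @return the table with normalized feature columns.
#' @export
apply_normalization <- function(table, stats) {
  if (!inherits(stats, "normalization_stats"))
    stopf("stats must come from fit_normalization()")
  missing <- setdiff(stats$features, colnames(table))
  if (length(missing))
    stopf("table lacks feature(s) named in the stats: %s",
          paste(missing, collapse = ", "))
  for (c in stats$features) {
    rng <- stats$max[[c]] - stats$min[[c]]
    table[[c]] <- if (rng == 0) rep(0, nrow(table))
                  else (table[[c]] - stats$min[[c]]) / rng
  }
  table
}

#' Interpolate or reject samples with missing timesteps
#'
#' A temporal sample with exactly one missing stage is completed: an
#' interior gap takes the per-feature arithmetic mean of its two
#' neighbours (linear interpolation between adjacent phenological
#' periods); an edge gap takes the nearest present stage's values. Samples
#' with more than one missing stage are rejected.
#'
#' Works on the sample's feature matrix (features x L) when present,
#' otherwise on the stage patches.
#'
#' @param sample a `temporal_sample`.
#' @return the completed sample (with a `fill_log` attribute naming what was
#'   filled), or an object of class `rejected_sample` carrying the reason.
#' @export
fill_missing_timesteps <- function(sample) {
  present <- sample$present %||% !vapply(sample$patches, is.null, logical(1))
  L <- length(present)
  n_missing <- sum(!present)
  if (n_missing == 0L) return(sample)
  if (n_missing > 1L) {
    return(structure(list(point_id = sample$point_id,
                          reason = sprintf("%d of %d timesteps missing (limit 1)",
                                           n_missing, L)),
                     class = "rejected_sample"))
  }
  slot <- which(!present)
  fill_one <- function(slots) {
    if (slot > 1L && slot < L) {
      a <- slots[[slot - 1L]]; b <- slots[[slot + 1L]]
      filled <- (a + b) / 2
      how <- "interior: mean of neighbours"
    } else {
      nb <- if (slot == 1L) slot + 1L else slot - 1L
      filled <- slots[[nb]]
      how <- sprintf("edge: nearest present stage %d", nb)
    }
    list(filled = filled, how = how)
  }
  if (!is.null(sample$features)) {
    slots <- lapply(seq_len(L), function(t) sample$features[, t])
    res <- fill_one(slots)
    sample$features[, slot] <- res$filled
  } else {
    res <- fill_one(sample$patches)
    filled <- res$filled
    attributes(filled) <- attributes(sample$patches[[if (slot == 1L) 2L else slot - 1L]])
    dim(filled) <- dim(res$filled)
    sample$patches[[slot]] <- filled
  }
  sample$present[slot] <- TRUE
  attr(sample, "fill_log") <- sprintf("stage %d filled (%s)", slot, res$how)
  sample
}
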