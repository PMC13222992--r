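## Sliding-window LAI map production and the four map-quality metrics:
## Moran's I, SSIM, coefficient of variation and spatial entropy.

#' Produce an LAI map by sliding-window inference
#'
#' Tiles the multi-date scene with windows of the given size and stride,
#' builds a temporal sample from each tile (one patch per date), extracts
#' features with `feature_cfg`, predicts with the trained model, and writes
#' the prediction onto the tile's footprint. Overlapping tiles are
#' averaged; partial edge tiles are covered by reflecting the scene at its
#' borders.
#'
#' @param trained a `trained_lai_model` (feature mode).
#' @param scenes list of L per-date H x W x 3 rasters (same units the model
#'   was trained on).
#' @param window tile side in pixels.
#' @param stride tile step in pixels (stride = window tiles without
#'   overlap).
#' @param feature_cfg the [feature_config()] used in training.
#' @param cell_size_cm ground cell size recorded on the map.
#' @return an `lai_map`: list with `grid` (H x W predictions), `cell_size`,
#'   `window`, `stride`.
#' @export
sliding_window_map <- function(trained, scenes, window, stride = window,
                               feature_cfg = feature_config(),
                               cell_size_cm = NULL) {
  h <- dim(scenes[[1]])[1]; w <- dim(scenes[[1]])[2]
  if (window > h || window > w)
    stopf("window %d exceeds scene %dx%d", window, h, w)
  L <- length(scenes)
  pad <- window                     # reflection pad so edge tiles are full
  scp <- lapply(scenes, reflect_pad, pad = pad)
  starts_r <- seq(1L, h, by = stride) + pad
  starts_c <- seq(1L, w, by = stride) + pad
  acc <- matrix(0, h, w); cnt <- matrix(0, h, w)
  tiles <- list(); footprints <- list()
  for (r0 in starts_r) for (c0 in starts_c) {
    patches <- lapply(seq_len(L), function(t) {
      p <- scp[[t]][r0:(r0 + window - 1L), c0:(c0 + window - 1L), , drop = FALSE]
      p
    })
    tiles[[length(tiles) + 1L]] <-
      structure(list(point_id = length(tiles) + 1L, patches = patches,
                     present = rep(TRUE, L), lai = NA_real_,
                     synthetic = FALSE, parent_points = integer(0)),
                class = "temporal_sample")
    footprints[[length(footprints) + 1L]] <- c(r0 - pad, c0 - pad)
  }
  tiles <- attach_sample_features(tiles, feature_cfg)
  pred <- predict(trained, tiles)
  for (i in seq_along(tiles)) {
    fr <- footprints[[i]]
    ri <- fr[1]:min(h, fr[1] + window - 1L)
    ci <- fr[2]:min(w, fr[2] + window - 1L)
    acc[ri, ci] <- acc[ri, ci] + pred[i]
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  grid <- acc / cnt
  structure(list(grid = grid, cell_size = cell_size_cm, window = window,
                 stride = stride), class = "lai_map")
}

## Reflect an H x W x C raster at all four borders by `pad` pixels.
reflect_pad <- function(x, pad) {
  h <- dim(x)[1]; w <- dim(x)[2]
  ri <- c(rev(seq_len(min(pad, h))), seq_len(h),
          h - seq_len(min(pad, h)) + 1L)
  ci <- c(rev(seq_len(min(pad, w))), seq_len(w),
          w - seq_len(min(pad, w)) + 1L)
  x[ri, ci, , drop = FALSE]
}

map_grid <- function(map) {
  if (inherits(map, "lai_map")) map$grid else as.matrix(map)
}

#' Global Moran's I of a raster
#'
#' Spatial autocorrelation under row-standardized contiguity weights:
#' queen (8 neighbours, the default) or rook (4 neighbours). +1 indicates
#' smooth spatial continuity, -1 perfect alternation.
#'
#' @param map an `lai_map` or numeric matrix (at least 2 cells).
#' @param weights `"queen"` or `"rook"`.
#' @return Moran's I; NA with an `undefined` attribute for zero-variance
#'   maps.
#' @export
morans_i <- function(map, weights = c("queen", "rook")) {
  weights <- match.arg(weights)
  x <- map_grid(map)
  n <- length(x)
  if (n < 2L) stopf("need at least 2 cells")
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) return(structure(NA_real_, undefined = TRUE))
  h <- nrow(x); w <- ncol(x)
  offsets <- if (weights == "rook") {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  ## neighbour count per cell (for row standardization)
  nb <- matrix(0, h, w)
  num_acc <- matrix(0, h, w)
  for (o in offsets) {
    rs <- seq_len(h) + o[1]; cs <- seq_len(w) + o[2]
    vr <- rs >= 1 & rs <= h; vc <- cs >= 1 & cs <= w
    nb[vr, vc] <- nb[vr, vc] + 1
    num_acc[vr, vc] <- num_acc[vr, vc] + z[rs[vr], cs[vc]]
  }
  ## row-standardized: each cell's weights sum to 1, so S0 = n and
  ## I = sum_i z_i * (sum_j w_ij z_j) / sum_i z_i^2
  sum(z * num_acc / nb) / denom
}

#' Structural similarity between two maps
#'
#' Mean local SSIM with a 7 x 7 uniform window, standard stabilizers
#' K1 = 0.01 and K2 = 0.03, and the dynamic range of the reference map.
#'
#' @param map,reference same-shape matrices or `lai_map`s (`reference` is
#'   the truth/high-resolution map).
#' @param window local window side (default 7).
#' @return mean SSIM in [-1, 1].
#' @export
ssim_map <- function(map, reference, window = 7L) {
  x <- map_grid(map); y <- map_grid(reference)
  if (!all(dim(x) == dim(y))) stopf("shape mismatch")
  Lr <- diff(range(y))
  if (Lr == 0) Lr <- 1
  C1 <- (0.01 * Lr)^2; C2 <- (0.03 * Lr)^2
  mu_x <- box_filter(x, window); mu_y <- box_filter(y, window)
  xx <- box_filter(x * x, window); yy <- box_filter(y * y, window)
  xy <- box_filter(x * y, window)
  var_x <- xx - mu_x^2; var_y <- yy - mu_y^2
  cov_xy <- xy - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + C1) * (2 * cov_xy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (var_x + var_y + C2))
  mean(s)
}

## Uniform (box) filter with window k over valid positions only; output is
## the same size using shrinking windows at the borders (normalized by the
## actual cell count).
box_filter <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  half <- (k - 1L) %/% 2L
  X1 <- apply(x, 2, cumsum)
  if (is.null(dim(X1))) X1 <- matrix(X1, nrow = h)
  S <- t(apply(X1, 1, cumsum))
  if (is.null(dim(S)) || nrow(S) != h) S <- matrix(S, nrow = h)
  cs <- matrix(0, h + 1L, w + 1L)
  cs[-1, -1] <- S
  i <- seq_len(h); j <- seq_len(w)
  r1 <- pmax(1L, i - half); r2 <- pmin(h, i + half)
  c1 <- pmax(1L, j - half); c2 <- pmin(w, j + half)
  sums <- cs[r2 + 1L, c2 + 1L, drop = FALSE] -
    cs[r1, c2 + 1L, drop = FALSE] -
    cs[r2 + 1L, c1, drop = FALSE] + cs[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / counts
}

#' Spatial coefficient of variation of a map
#'
#' Population standard deviation divided by the mean of the predicted
#' values; lower values indicate a more stable spatial distribution.
#'
#' @param map an `lai_map` or matrix with nonzero mean.
#' @return the CV.
#' @export
spatial_cv <- function(map) {
  x <- map_grid(map)
  m <- mean(x)
  if (m == 0) stopf("zero-mean map: CV undefined")
  sqrt(mean((x - m)^2)) / m
}

#' Spatial entropy of a map
#'
#' Shannon entropy (natural log) of the equal-width-binned value histogram
#' over the map's range; 0 for a constant map, at most log(bins).
#'
#' @param map an `lai_map` or matrix.
#' @param bins number of histogram bins (default 64).
#' @return entropy in nats.
#' @export
spatial_entropy <- function(map, bins = 64L) {
  x <- as.vector(map_grid(map))
  if (!length(x)) stopf("empty map")
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  b <- pmin(bins, pmax(1L, floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1L))
  p <- tabulate(b, bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mean-filter smoothing of a map
#'
#' 3 x 3 moving-average smoother (shrinking windows at the borders), used
#' when probing how smoothing moves the spatial metrics.
#'
#' @param map an `lai_map` or matrix.
#' @return smoothed matrix.
#' @export
smooth_map <- function(map) {
  x <- map_grid(map)
  box_filter(x, 3L)
}
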