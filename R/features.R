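## RGB spectral parameters, GLCM texture statistics, the window-footprint
## helper and the window/displacement sensitivity sweep.

spectral_feature_names <- c(
  "R", "G", "B", "RCC", "GCC", "BCC", "GRRI", "GBRI", "RBRI", "GRVI",
  "NDI", "WI", "IKAW", "GLI", "VARI", "EXR", "EXG", "EXB", "IPCA", "CIVE",
  "SDGB", "SDRB", "SDRG", "MRGB", "SGRB", "CI")

texture_stat_names <- c("MEA", "VAR", "HOM", "CON", "DIS", "ENT", "SEC", "COR")

## Band-major texture names: MEA_R, VAR_R, ..., COR_R, MEA_G, ...
texture_feature_names <- function(bands = c("R", "G", "B")) {
  unlist(lapply(bands, function(b) paste(texture_stat_names, b, sep = "_")),
         use.names = FALSE)
}

#' Names of all candidate features
#'
#' 26 spectral parameters followed by the 8 GLCM statistics for each of the
#' three bands (band-major order), 50 names in total. This is the stable
#' column ordering used by [extract_patch_features()] and the feature-table
#' builders.
#' @return character vector of feature names.
#' @export
all_feature_names <- function() c(spectral_feature_names, texture_feature_names())

## Safe ratio: zero denominator -> 0, counted per feature.
safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Compute the 26 spectral parameters of an RGB patch
#'
#' The three band values and 23 visible-band vegetation indices: chromatic
#' coordinates (RCC, GCC, BCC), band ratios (GRRI, GBRI, RBRI), normalized
#' differences (GRVI, NDI, IKAW, GLI, VARI), excess-colour indices (EXR,
#' EXG, EXB, SGRB), the Woebbecke index, IPCA and CIVE composites, simple
#' band differences (SDGB, SDRB, SDRG), the band mean MRGB and the
#' coloration index CI. By default band means over the patch are taken
#' first and the indices computed on the three means (one vector per
#' patch); `aggregation = "pixelwise"` instead computes per-pixel index
#' maps and averages them.
#'
#' Any ratio with a zero denominator evaluates to 0 and increments the
#' per-feature degenerate counter stored in the `"degenerate"` attribute
#' (NDI carries its own +0.01 guard and never triggers it).
#'
#' @param patch H x W x 3 array (DN or reflectance).
#' @param aggregation `"mean_bands"` (default) or `"pixelwise"`.
#' @return named numeric vector of length 26.
#' @export
compute_spectral_features <- function(patch,
                                      aggregation = c("mean_bands", "pixelwise")) {
  aggregation <- match.arg(aggregation)
  d <- dim(patch)
  if (is.null(d) || length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L)
    stopf("patch must be a non-empty H x W x 3 array")
  if (aggregation == "mean_bands") {
    v <- spectral_from_rgb(mean(patch[, , 1]), mean(patch[, , 2]),
                           mean(patch[, , 3]))
  } else {
    per_px <- mapply(function(r, g, b) spectral_from_rgb(r, g, b),
                     patch[, , 1], patch[, , 2], patch[, , 3])
    v <- rowMeans(per_px)
    attr(v, "degenerate") <- NULL
    names(v) <- spectral_feature_names
  }
  v
}

spectral_from_rgb <- function(R, G, B) {
  degen <- integer(0)
  div <- function(name, num, den) {
    if (den == 0) { degen <<- c(degen, stats::setNames(1L, name)); return(0) }
    num / den
  }
  s <- R + G + B
  RCC <- div("RCC", R, s); GCC <- div("GCC", G, s); BCC <- div("BCC", B, s)
  v <- c(
    R = R, G = G, B = B,
    RCC = RCC, GCC = GCC, BCC = BCC,
    GRRI = div("GRRI", G, R),
    GBRI = div("GBRI", G, B),
    RBRI = div("RBRI", R, B),
    GRVI = div("GRVI", G - R, G + R),
    NDI = (RCC - GCC) / (RCC + GCC + 0.01),
    WI = div("WI", G - B, R - G),
    IKAW = div("IKAW", R - B, R + B),
    GLI = div("GLI", 2 * G - R - B, 2 * G + R + B),
    VARI = div("VARI", G - R, G + R - B),
    EXR = 1.4 * RCC - GCC,
    EXG = 2 * GCC - RCC - BCC,
    EXB = 1.4 * BCC - GCC,
    IPCA = 0.994 * abs(R - B) + 0.961 * abs(G - B) + 0.914 * abs(G - R),
    CIVE = 0.441 * R - 0.881 * G + 0.385 * B + 18.78745,
    SDGB = G - B,
    SDRB = R - B,
    SDRG = R - G,
    MRGB = (R + G + B) / 3,
    SGRB = 2 * G - R - B,
    CI = div("CI", R - B, R))
  attr(v, "degenerate") <- degen
  v
}

#' Compute a gray-level co-occurrence matrix
#'
#' Quantizes the window to `levels` equal-width gray levels over the
#' window's observed value range, accumulates symmetric co-occurrence
#' counts for the displacement vector, and normalizes to a joint
#' probability matrix.
#'
#' @param band_window numeric matrix (one band).
#' @param levels number of gray levels Ng (default 32).
#' @param displacement integer (rows, cols) offset; the default c(2, 2) is
#'   a diagonal offset of 2 rows and 2 columns.
#' @return a `glcm` object: Ng x Ng probability matrix with metadata.
#' @export
compute_glcm <- function(band_window, levels = 32L, displacement = c(2L, 2L)) {
  if (!is.matrix(band_window)) band_window <- as.matrix(band_window)
  h <- nrow(band_window); w <- ncol(band_window)
  dr <- abs(as.integer(displacement[1])); dc <- abs(as.integer(displacement[2]))
  if (levels < 2L) stopf("levels (Ng) must be >= 2")
  if (h <= dr || w <= dc)
    stopf("window %dx%d smaller than displacement (%d, %d)", h, w, dr, dc)
  q <- quantize_band(band_window, levels)
  a <- q[seq_len(h - dr), seq_len(w - dc), drop = FALSE]
  b <- q[seq_len(h - dr) + dr, seq_len(w - dc) + dc, drop = FALSE]
  counts <- tabulate((a - 1L) * levels + b, nbins = levels * levels) +
            tabulate((b - 1L) * levels + a, nbins = levels * levels)
  P <- matrix(counts / sum(counts), levels, levels)
  structure(list(P = P, levels = levels, displacement = c(dr, dc),
                 window = c(h, w)), class = "glcm")
}

## Equal-width quantization over the observed range; constant input maps to
## level 1. Adding a constant to all pixels shifts the range with them, so
## the quantized image is shift-invariant.
quantize_band <- function(x, levels) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(matrix(1L, nrow(x), ncol(x)))
  q <- floor((x - rng[1]) / (rng[2] - rng[1]) * levels) + 1L
  q[q > levels] <- levels
  matrix(as.integer(q), nrow(x), ncol(x))
}

#' Haralick statistics of a GLCM
#'
#' Mean, variance, homogeneity, contrast, dissimilarity, entropy, second
#' moment and correlation of the joint probability matrix, using 0-based
#' level indices. Entropy uses the natural logarithm with 0 log 0 := 0;
#' correlation is 0 when either marginal SD is 0.
#'
#' @param glcm a [compute_glcm()] result.
#' @return named numeric vector MEA, VAR, HOM, CON, DIS, ENT, SEC, COR.
#' @export
compute_texture_features <- function(glcm) {
  P <- if (inherits(glcm, "glcm")) glcm$P else as.matrix(glcm)
  ng <- nrow(P)
  i <- matrix(0:(ng - 1), ng, ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum((0:(ng - 1)) * px); mu_y <- sum((0:(ng - 1)) * py)
  sd_x <- sqrt(sum(((0:(ng - 1)) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((0:(ng - 1)) - mu_y)^2 * py))
  mea <- sum(i * P)
  nz <- P > 0
  c(MEA = mea,
    VAR = sum((i - mea)^2 * P),
    HOM = sum(P / (1 + (i - j)^2)),
    CON = sum((i - j)^2 * P),
    DIS = sum(abs(i - j) * P),
    ENT = -sum(P[nz] * log(P[nz])),
    SEC = sum(P^2),
    COR = if (sd_x * sd_y == 0) 0 else
      (sum(i * j * P) - mu_x * mu_y) / (sd_x * sd_y))
}

#' Physical footprint of a pixel window
#'
#' @param window_px window side length in pixels.
#' @param resolution_cm_per_px ground resolution in cm/pixel.
#' @return side length in cm (e.g. 9 px at 0.83 cm/px -> 7.47 cm).
#' @export
window_footprint <- function(window_px, resolution_cm_per_px) {
  if (window_px <= 0 || resolution_cm_per_px <= 0)
    stopf("window_px and resolution must be positive")
  window_px * resolution_cm_per_px
}

#' Feature-extraction configuration
#'
#' @param features feature-name subset (default: all 50 candidates).
#' @param glcm_window GLCM processing window side in pixels (default 9).
#' @param glcm_displacement displacement vector (default c(2, 2)).
#' @param glcm_levels gray levels Ng (default 32).
#' @param aggregation spectral aggregation mode, see
#'   [compute_spectral_features()].
#' @return a `feature_config` list.
#' @export
feature_config <- function(features = all_feature_names(),
                           glcm_window = 9L,
                           glcm_displacement = c(2L, 2L),
                           glcm_levels = 32L,
                           aggregation = "mean_bands") {
  unknown <- setdiff(features, all_feature_names())
  if (length(unknown))
    stopf("unknown feature name(s): %s", paste(unknown, collapse = ", "))
  structure(list(features = features, glcm_window = as.integer(glcm_window),
                 glcm_displacement = as.integer(glcm_displacement),
                 glcm_levels = as.integer(glcm_levels),
                 aggregation = aggregation),
            class = "feature_config")
}

#' Extract the configured feature vector from a patch
#'
#' Concatenates the 26 spectral parameters with the per-band GLCM texture
#' statistics. Texture is computed on a grid of non-overlapping
#' `glcm_window`-sized windows tiling the patch and the statistics averaged
#' over windows; a patch smaller than the window uses a single window
#' covering the whole patch.
#'
#' @param patch H x W x 3 array.
#' @param config a [feature_config()].
#' @return named numeric vector ordered as in `config$features`.
#' @export
extract_patch_features <- function(patch, config = feature_config()) {
  if (!inherits(config, "feature_config")) stopf("config must be a feature_config")
  spec <- compute_spectral_features(patch, aggregation = config$aggregation)
  tex_names <- texture_feature_names()
  need_tex <- any(config$features %in% tex_names)
  tex <- NULL
  if (need_tex) {
    tex <- numeric(0)
    for (k in 1:3) {
      band <- patch[, , k]
      stats_mat <- glcm_over_windows(band, config)
      names(stats_mat) <- paste(texture_stat_names, c("R", "G", "B")[k], sep = "_")
      tex <- c(tex, stats_mat)
    }
  }
  full <- c(spec, tex)
  out <- full[config$features]
  names(out) <- config$features
  out
}

## Average Haralick statistics over a non-overlapping tiling of windows.
glcm_over_windows <- function(band, config) {
  h <- nrow(band); w <- ncol(band)
  win <- config$glcm_window
  dr <- config$glcm_displacement[1]; dc <- config$glcm_displacement[2]
  if (h < win || w < win) {
    ## single window covering the whole (small) patch
    g <- compute_glcm(band, config$glcm_levels, config$glcm_displacement)
    return(compute_texture_features(g))
  }
  r0 <- seq(1L, h - win + 1L, by = win)
  c0 <- seq(1L, w - win + 1L, by = win)
  acc <- NULL
  n <- 0L
  for (r in r0) for (cc in c0) {
    sub <- band[r:(r + win - 1L), cc:(cc + win - 1L)]
    st <- compute_texture_features(
      compute_glcm(sub, config$glcm_levels, config$glcm_displacement))
    acc <- if (is.null(acc)) st else acc + st
    n <- n + 1L
  }
  acc / n
}

#' Window/displacement sensitivity sweep for texture features
#'
#' For every combination of GLCM window size and displacement, computes the
#' texture features of each sample's final-stage patch and their Pearson
#' correlation with the LAI labels.
#'
#' @param dataset list of `temporal_sample` objects with patches and labels.
#' @param windows vector of window sizes (default c(3, 5, 7, 9, 11)).
#' @param displacements vector of displacement magnitudes (default 1:3),
#'   each used as the diagonal vector (d, d).
#' @param levels gray levels (default 32).
#' @return data.frame with columns window, displacement, feature, r and
#'   mean_abs_r (per-setting mean of |r| over features, repeated per row).
#' @export
texture_sensitivity_sweep <- function(dataset,
                                      windows = c(3L, 5L, 7L, 9L, 11L),
                                      displacements = 1:3,
                                      levels = 32L) {
  lai <- vapply(dataset, function(s) s$lai, numeric(1))
  L <- length(dataset[[1]]$patches)
  out <- list()
  for (win in windows) for (d in displacements) {
    if (win <= d) {
      ## geometrically empty setting (no pixel pair fits the window):
      ## reported in the grid with NA correlations
      out[[length(out) + 1L]] <- data.frame(
        window = win, displacement = d, feature = texture_feature_names(),
        r = NA_real_, mean_abs_r = NA_real_, row.names = NULL)
      next
    }
    cfg <- feature_config(features = texture_feature_names(),
                          glcm_window = win,
                          glcm_displacement = c(d, d), glcm_levels = levels)
    feats <- t(vapply(dataset, function(s)
      extract_patch_features(s$patches[[L]], cfg),
      numeric(length(cfg$features))))
    r <- vapply(seq_len(ncol(feats)), function(j) {
      x <- feats[, j]
      if (stats::sd(x) == 0) 0 else stats::cor(x, lai)
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      window = win, displacement = d, feature = colnames(feats), r = r,
      mean_abs_r = mean(abs(r)), row.names = NULL)
  }
  do.call(rbind, out)
}
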