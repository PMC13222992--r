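## Synthetic orchard scenes, calibration-panel observations and
## multi-temporal labelled sample sets. The generator defines the study
## conditions every downstream stage is tested against: a wide-row orchard
## of elliptical canopies over bare soil, a monotone greenness-vs-LAI link,
## LAI-coupled internal canopy texture, logistic per-point LAI trajectories
## over the phenological stages, and per-date global illumination gain/bias
## on top of a nonlinear camera response.

#' Scene and dataset configuration for the synthetic orchard generator
#'
#' All downstream modules are exercised on imagery drawn from this
#' generator. Canopies are rendered as ellipses on a regular row grid with
#' Gaussian-blob internal texture; the expected green reflectance of canopy
#' pixels is a strictly increasing logistic function of the local true LAI,
#' and the texture amplitude scales with LAI so that co-occurrence contrast
#' carries signal too. Each acquisition date applies a global multiplicative
#' gain and additive bias in DN space, the minimal artifact that histogram
#' matching must remove.
#'
#' @param scene_size integer (rows, cols) of the full scene in pixels.
#' @param resolution ground resolution in cm/pixel (default 0.83).
#' @param row_spacing_m,plant_spacing_m orchard row and in-row plant spacing
#'   in metres (defaults 4.5 and 1.5, a wide-row narrow-plant pattern).
#' @param n_points number of sampling points (trees) to generate.
#' @param n_stages number of phenological stages L (default 3).
#' @param stage_names names of the stages, length `n_stages`.
#' @param lai_range range of final-stage LAI labels (default c(3.3, 5.2)).
#' @param green_range canopy green reflectance at the low/high end of the
#'   logistic greenness-vs-LAI link.
#' @param green_slope slope of the logistic link (per LAI unit).
#' @param texture_amp amplitude of the zero-mean Gaussian-blob canopy
#'   texture at the midpoint LAI; the realised amplitude is proportional to
#'   the local LAI. Set 0 for noise-free imagery.
#' @param dn_noise additive sensor noise SD in DN units.
#' @param gain_range,bias_range per-date global illumination gain and bias
#'   ranges applied in DN space after rendering.
#' @param soil_reflectance background soil reflectance, length 3 (R, G, B).
#' @param dn_scale,gamma camera response model: DN = dn_scale * reflectance^gamma.
#' @param patch_px side length of per-point patch crops in pixels.
#' @param sigma_point SD of the per-point random effect on the early-stage
#'   LAI trajectory (LAI units).
#' @param missing_rate probability that any (point, stage) observation is
#'   missing, applied independently.
#' @param seed integer seed; identical seed + config gives bit-identical
#'   output.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(scene_size = c(1200L, 1200L),
                         resolution = 0.83,
                         row_spacing_m = 4.5,
                         plant_spacing_m = 1.5,
                         n_points = 12L,
                         n_stages = 3L,
                         stage_names = c("growth", "maturity", "fruit_bearing"),
                         lai_range = c(3.3, 5.2),
                         green_range = c(0.15, 0.55),
                         green_slope = 1.6,
                         texture_amp = 0.04,
                         dn_noise = 1.0,
                         gain_range = c(0.9, 1.1),
                         bias_range = c(-8, 8),
                         soil_reflectance = c(0.32, 0.26, 0.20),
                         dn_scale = 255,
                         gamma = 0.8,
                         patch_px = 48L,
                         sigma_point = 0.12,
                         missing_rate = 0,
                         seed = 1L) {
  cfg <- list(scene_size = as.integer(scene_size), resolution = resolution,
              row_spacing_m = row_spacing_m, plant_spacing_m = plant_spacing_m,
              n_points = as.integer(n_points), n_stages = as.integer(n_stages),
              stage_names = stage_names, lai_range = lai_range,
              green_range = green_range, green_slope = green_slope,
              texture_amp = texture_amp, dn_noise = dn_noise,
              gain_range = gain_range, bias_range = bias_range,
              soil_reflectance = soil_reflectance, dn_scale = dn_scale,
              gamma = gamma, patch_px = as.integer(patch_px),
              sigma_point = sigma_point, missing_rate = missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  if (!is_scalar_num(cfg$resolution) || cfg$resolution <= 0)
    stopf("resolution must be > 0 (got %s)", cfg$resolution)
  if (cfg$n_stages < 1L) stopf("n_stages (L) must be >= 1")
  if (length(cfg$stage_names) != cfg$n_stages)
    stopf("stage_names must have length n_stages")
  if (any(cfg$lai_range <= 0) || any(cfg$lai_range > 10) ||
      diff(cfg$lai_range) < 0)
    stopf("lai_range must be an increasing range within (0, 10]")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stopf("missing_rate must be in [0, 1]")
  if (cfg$patch_px < 4L) stopf("patch_px must be at least 4")
  invisible(cfg)
}

## Expected canopy green reflectance as a function of LAI: strictly
## increasing logistic link anchored on the configured LAI range.
greenness_link <- function(lai, cfg) {
  mid <- mean(cfg$lai_range)
  lo <- cfg$green_range[1]; hi <- cfg$green_range[2]
  lo + (hi - lo) * stats::plogis(cfg$green_slope * (lai - mid))
}

## Per-point LAI trajectory over stages: logistic rise in stage index,
## anchored so that the final stage equals the drawn label; a point-level
## random effect perturbs the starting value. Values stay inside lai_range.
lai_trajectory <- function(final_lai, L, cfg, point_eps) {
  if (L == 1L) return(final_lai)
  t <- seq_len(L)
  t0 <- (L + 1) / 2
  w <- stats::plogis(1.5 * (t - t0))
  w <- (w - w[1]) / (w[L] - w[1])            # 0 at first stage, 1 at last
  start <- cfg$lai_range[1] + 0.15 * (final_lai - cfg$lai_range[1]) + point_eps
  start <- min(max(start, cfg$lai_range[1]), final_lai)
  start + (final_lai - start) * w
}

## Zero-mean Gaussian-blob texture field: a few dozen random blobs whose
## superposition is recentred to mean zero so the monotone greenness link is
## preserved exactly in expectation.
blob_field <- function(h, w, n_blobs = 40L, sigma_px = 3) {
  f <- matrix(0, h, w)
  if (n_blobs == 0L) return(f)
  cy <- stats::runif(n_blobs, 1, h)
  cx <- stats::runif(n_blobs, 1, w)
  amp <- stats::rnorm(n_blobs)
  ys <- seq_len(h); xs <- seq_len(w)
  for (b in seq_len(n_blobs)) {
    gy <- exp(-((ys - cy[b])^2) / (2 * sigma_px^2))
    gx <- exp(-((xs - cx[b])^2) / (2 * sigma_px^2))
    f <- f + amp[b] * outer(gy, gx)
  }
  f - mean(f)
}

## Render one canopy patch in reflectance units (H x W x 3 in [0,1]).
## Canopy = centred ellipse; inside, green follows the LAI link and carries
## LAI-proportional blob texture; red/blue are darker canopy constants.
render_canopy_patch <- function(lai, cfg, jitter = c(0, 0)) {
  p <- cfg$patch_px
  ys <- matrix(seq_len(p), p, p)
  xs <- t(ys)
  cy <- (p + 1) / 2 + jitter[1]; cx <- (p + 1) / 2 + jitter[2]
  a <- 0.42 * p; b <- 0.36 * p
  inside <- ((ys - cy) / a)^2 + ((xs - cx) / b)^2 <= 1
  soil <- cfg$soil_reflectance
  img <- array(0, c(p, p, 3))
  for (k in 1:3) img[, , k] <- soil[k]
  g <- greenness_link(lai, cfg)
  amp <- cfg$texture_amp * lai / mean(cfg$lai_range)
  tex <- if (amp > 0) amp * blob_field(p, p) else matrix(0, p, p)
  canopy <- list(r = 0.12, g = g, b = 0.08)
  img[, , 1][inside] <- canopy$r + 0.4 * tex[inside]
  img[, , 2][inside] <- canopy$g + tex[inside]
  img[, , 3][inside] <- canopy$b + 0.3 * tex[inside]
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

## Camera response: reflectance -> DN, and per-date illumination.
reflectance_to_dn <- function(img, cfg) cfg$dn_scale * img^cfg$gamma

apply_date_illumination <- function(dn, gain, bias) gain * dn + bias

new_rgb_patch <- function(values, units, cfg, stage = NA, date = NA) {
  structure(values, class = "rgb_patch", units = units,
            resolution = cfg$resolution, stage = stage, date = date)
}

#' Generate a full synthetic orchard scene bundle
#'
#' Lays canopies on a regular row grid (row and plant spacing taken from the
#' config, converted through the ground resolution), renders one scene per
#' phenological stage in DN units with per-date illumination gain/bias, and
#' crops a patch around every sampling point. A truth LAI field on the scene
#' grid assigns each pixel the LAI of its nearest sampling point, so
#' patch means of the truth field reproduce the point labels.
#'
#' @param config a [scene_config()].
#' @return a `scene_bundle`: list with `scenes` (per stage, H x W x 3 DN
#'   arrays), `patches` (per point, list of per-stage `rgb_patch`),
#'   `lai` (n_points x L matrix of true LAI), `labels` (final-stage LAI),
#'   `points` (data.frame of point_id, row, col), `truth_field` (per stage,
#'   H x W LAI grid), `illumination` (per-date gain/bias actually applied).
#' @export
generate_orchard_scene <- function(config) {
  cfg <- validate_scene_config(config)
  h <- cfg$scene_size[1]; w <- cfg$scene_size[2]
  px_per_m <- 100 / cfg$resolution
  row_px <- cfg$row_spacing_m * px_per_m
  plant_px <- cfg$plant_spacing_m * px_per_m
  half <- cfg$patch_px / 2
  grid_seq <- function(from, to, by) {
    if (to < from) numeric(0) else seq(from, to, by = by)
  }
  rows <- grid_seq(half + row_px / 2, h - half, row_px)
  cols <- grid_seq(half + plant_px / 2, w - half, plant_px)
  if (length(rows) < 1L || length(cols) < 1L ||
      length(rows) * length(cols) < cfg$n_points)
    stopf("scene %dx%d px holds %d canopy positions; %d points requested",
          h, w, length(rows) * length(cols), cfg$n_points)
  grid <- expand.grid(row = rows, col = cols)
  grid <- grid[seq_len(cfg$n_points), , drop = FALSE]

  with_seed(cfg$seed, {
    L <- cfg$n_stages
    finals <- stats::runif(cfg$n_points, cfg$lai_range[1], cfg$lai_range[2])
    eps <- stats::rnorm(cfg$n_points, 0, cfg$sigma_point)
    lai <- t(vapply(seq_len(cfg$n_points), function(i)
      lai_trajectory(finals[i], L, cfg, eps[i]), numeric(L)))
    lai <- matrix(lai, cfg$n_points, L)
    gains <- stats::runif(L, cfg$gain_range[1], cfg$gain_range[2])
    biases <- stats::runif(L, cfg$bias_range[1], cfg$bias_range[2])

    ## nearest-point ownership for the truth field
    ys <- matrix(seq_len(h), h, w); xs <- t(matrix(seq_len(w), w, h))
    owner <- matrix(1L, h, w)
    best <- (ys - grid$row[1])^2 + (xs - grid$col[1])^2
    if (cfg$n_points > 1L) for (i in 2:cfg$n_points) {
      d <- (ys - grid$row[i])^2 + (xs - grid$col[i])^2
      upd <- d < best
      owner[upd] <- i; best[upd] <- d[upd]
    }

    scenes <- vector("list", L)
    truth <- vector("list", L)
    patches <- rep(list(vector("list", L)), cfg$n_points)
    for (t in seq_len(L)) {
      scene <- array(0, c(h, w, 3))
      for (k in 1:3) scene[, , k] <- cfg$soil_reflectance[k]
      for (i in seq_len(cfg$n_points)) {
        p <- render_canopy_patch(lai[i, t], cfg)
        r0 <- round(grid$row[i] - half); c0 <- round(grid$col[i] - half)
        ri <- r0 + seq_len(cfg$patch_px) - 1L
        ci <- c0 + seq_len(cfg$patch_px) - 1L
        scene[ri, ci, ] <- p
      }
      dn <- reflectance_to_dn(scene, cfg)
      if (cfg$dn_noise > 0)
        dn <- dn + array(stats::rnorm(length(dn), 0, cfg$dn_noise), dim(dn))
      dn <- apply_date_illumination(dn, gains[t], biases[t])
      scenes[[t]] <- new_rgb_patch(dn, "dn", cfg, stage = cfg$stage_names[t],
                                   date = t)
      tf <- matrix(lai[owner, t], h, w)
      truth[[t]] <- tf
      for (i in seq_len(cfg$n_points)) {
        r0 <- round(grid$row[i] - half); c0 <- round(grid$col[i] - half)
        ri <- r0 + seq_len(cfg$patch_px) - 1L
        ci <- c0 + seq_len(cfg$patch_px) - 1L
        patches[[i]][[t]] <- new_rgb_patch(scenes[[t]][ri, ci, , drop = FALSE],
                                           "dn", cfg,
                                           stage = cfg$stage_names[t], date = t)
      }
    }
    structure(list(scenes = scenes, truth_field = truth, patches = patches,
                   lai = lai, labels = lai[, L],
                   points = data.frame(point_id = seq_len(cfg$n_points),
                                       row = grid$row, col = grid$col),
                   illumination = data.frame(date = seq_len(L), gain = gains,
                                             bias = biases),
                   config = cfg),
              class = "scene_bundle")
  })
}

#' Generate calibration-panel observations
#'
#' Emulates photographing a grayscale reflectance step panel: per band, an
#' ordered sequence of (DN, reflectance) pairs following the camera's
#' nonlinear response DN = dn_scale * reflectance^gamma, optionally with
#' additive DN noise.
#'
#' @param config a [scene_config()] (camera model and seed are read from it).
#' @param n_steps number of panel steps (default 24).
#' @param noise_sd DN noise SD on the panel readings (default 0, i.e. exact).
#' @return a `panel_observations` object: list of per-band data.frames with
#'   columns `dn` and `reflectance`.
#' @export
generate_panel_observations <- function(config, n_steps = 24L, noise_sd = 0) {
  cfg <- validate_scene_config(config)
  if (n_steps < 2L) stopf("a panel needs at least 2 steps")
  refl <- seq(0.02, 0.95, length.out = n_steps)
  with_seed(child_seed(cfg$seed, "panel"), {
    bands <- lapply(c("R", "G", "B"), function(b) {
      dn <- cfg$dn_scale * refl^cfg$gamma
      if (noise_sd > 0) {
        dn <- dn + stats::rnorm(n_steps, 0, noise_sd)
        dn <- cummax(dn)             # readings stay ordered with the steps
      }
      data.frame(dn = dn, reflectance = refl)
    })
    names(bands) <- c("R", "G", "B")
    structure(bands, class = "panel_observations",
              dn_scale = cfg$dn_scale, gamma = cfg$gamma)
  })
}

#' Generate a multi-temporal labelled sample set
#'
#' Renders, for each sampling point, one canopy patch per phenological stage
#' (DN units, per-date illumination applied) and attaches the final-stage
#' LAI label. Per-point LAI trajectories follow a logistic growth curve with
#' a point-level random effect. Missingness, if requested, is applied to
#' each (point, stage) independently; samples keep `present` flags so the
#' preprocessing module can interpolate or reject them.
#'
#' @param config a [scene_config()]; `n_points`, `missing_rate` and the
#'   camera/illumination model are taken from it.
#' @return list of `temporal_sample` objects, each with fields `point_id`,
#'   `patches` (length L, NULL where missing), `present`, `lai` (label),
#'   `lai_trajectory`, `stages`, `synthetic` and `parent_points`.
#' @export
generate_time_series_dataset <- function(config) {
  cfg <- validate_scene_config(config)
  with_seed(cfg$seed, {
    L <- cfg$n_stages
    n <- cfg$n_points
    finals <- stats::runif(n, cfg$lai_range[1], cfg$lai_range[2])
    eps <- stats::rnorm(n, 0, cfg$sigma_point)
    gains <- stats::runif(L, cfg$gain_range[1], cfg$gain_range[2])
    biases <- stats::runif(L, cfg$bias_range[1], cfg$bias_range[2])
    lapply(seq_len(n), function(i) {
      traj <- lai_trajectory(finals[i], L, cfg, eps[i])
      present <- stats::runif(L) >= cfg$missing_rate
      patches <- vector("list", L)
      for (t in seq_len(L)) {
        if (!present[t]) next
        refl <- render_canopy_patch(traj[t], cfg)
        dn <- reflectance_to_dn(refl, cfg)
        if (cfg$dn_noise > 0)
          dn <- dn + array(stats::rnorm(length(dn), 0, cfg$dn_noise), dim(dn))
        dn <- apply_date_illumination(dn, gains[t], biases[t])
        patches[[t]] <- new_rgb_patch(dn, "dn", cfg,
                                      stage = cfg$stage_names[t], date = t)
      }
      structure(list(point_id = i, patches = patches, present = present,
                     lai = finals[i], lai_trajectory = traj,
                     stages = cfg$stage_names, synthetic = FALSE,
                     parent_points = i),
                class = "temporal_sample")
    })
  })
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("scene_config: %dx%d px @ %.2f cm/px, %d points, L=%d, LAI [%.1f, %.1f], seed %d\n",
              x$scene_size[1], x$scene_size[2], x$resolution, x$n_points,
              x$n_stages, x$lai_range[1], x$lai_range[2], x$seed))
  invisible(x)
}
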