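# Fixtures built in code: tiny sample sets, planted-signal tables, and
# brute-force oracles kept independent of the implementation paths they
# check.

# A fast low-resolution scene config for tests (coarse ground resolution,
# tiny patches) -- the statistical structure is the generator's default.
tiny_scene_config <- function(...) {
  args <- list(scene_size = c(300L, 300L), resolution = 5, n_points = 8L,
               patch_px = 16L, seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(scene_config, args)
}

# Feature-mode samples with a planted linear signal in the features.
make_feature_samples <- function(n = 60L, F = 8L, L = 3L, noise = 0.05,
                                 seed = 1L, signal_stage = NULL) {
  set.seed(seed)
  X <- array(rnorm(n * F * L), c(n, F, L))
  y <- if (is.null(signal_stage)) {
    4 + 0.4 * rowMeans(X[, 1, ]) + 0.3 * rowMeans(X[, 2, ]) +
      rnorm(n, 0, noise)
  } else {
    4 + 0.4 * X[, 1, signal_stage] + 0.3 * X[, 2, signal_stage] +
      rnorm(n, 0, noise)
  }
  lapply(seq_len(n), function(i) {
    structure(list(point_id = i,
                   features = matrix(X[i, , ], F, L,
                                     dimnames = list(paste0("f", seq_len(F)),
                                                     NULL)),
                   lai = y[i], synthetic = FALSE, parent_points = i),
              class = "temporal_sample")
  })
}

# Patch-mode samples: uniform-valued patches so pixel bookkeeping is exact.
make_patch_samples <- function(n = 6L, px = 12L, L = 3L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    patches <- lapply(seq_len(L), function(t)
      array(i * 10 + t + runif(px * px * 3), c(px, px, 3)))
    structure(list(point_id = i, patches = patches,
                   present = rep(TRUE, L), lai = 3.3 + 0.2 * i,
                   synthetic = FALSE, parent_points = i),
              class = "temporal_sample")
  })
}

# Brute-force GLCM oracle: explicit pair enumeration on the quantized
# window, symmetric accumulation, then direct Table-style statistics.
oracle_glcm <- function(window, levels, displacement) {
  q <- uavlai:::quantize_band(as.matrix(window), levels)
  h <- nrow(q); w <- ncol(q)
  dr <- displacement[1]; dc <- displacement[2]
  P <- matrix(0, levels, levels)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
      P[q[r, c], q[r2, c2]] <- P[q[r, c], q[r2, c2]] + 1
      P[q[r2, c2], q[r, c]] <- P[q[r2, c2], q[r, c]] + 1
    }
  }
  P / sum(P)
}

oracle_haralick <- function(P) {
  ng <- nrow(P)
  mea <- 0; con <- 0; dis <- 0; hom <- 0; ent <- 0; sec <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    ii <- i - 1; jj <- j - 1
    mea <- mea + ii * p
    con <- con + (ii - jj)^2 * p
    dis <- dis + abs(ii - jj) * p
    hom <- hom + p / (1 + (ii - jj)^2)
    if (p > 0) ent <- ent - p * log(p)
    sec <- sec + p^2
  }
  vr <- 0
  for (i in 1:ng) for (j in 1:ng) vr <- vr + ((i - 1) - mea)^2 * P[i, j]
  px <- rowSums(P); py <- colSums(P)
  mx <- sum((0:(ng - 1)) * px); my <- sum((0:(ng - 1)) * py)
  sx <- sqrt(sum(((0:(ng - 1)) - mx)^2 * px))
  sy <- sqrt(sum(((0:(ng - 1)) - my)^2 * py))
  cr <- 0
  if (sx * sy > 0) {
    for (i in 1:ng) for (j in 1:ng)
      cr <- cr + (i - 1) * (j - 1) * P[i, j]
    cr <- (cr - mx * my) / (sx * sy)
  }
  c(MEA = mea, VAR = vr, HOM = hom, CON = con, DIS = dis, ENT = ent,
    SEC = sec, COR = cr)
}

# Brute-force Moran's I: explicit double sum over a row-standardized
# contiguity weight matrix.
oracle_morans_i <- function(x, rook = FALSE) {
  h <- nrow(x); w <- ncol(x); n <- h * w
  idx <- function(r, c) (c - 1) * h + r
  W <- matrix(0, n, n)
  for (r in 1:h) for (c in 1:w) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (rook && abs(dr) + abs(dc) != 1) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w)
        W[idx(r, c), idx(r2, c2)] <- 1
    }
  }
  W <- W / rowSums(W)
  z <- as.vector(x) - mean(x)
  s0 <- sum(W)
  (n / s0) * sum(W * outer(z, z)) / sum(z^2)
}

# Naive loop regression metrics.
oracle_metrics <- function(y, p) {
  n <- length(y)
  ssr <- 0; sst <- 0; sae <- 0; sape <- 0; sse <- 0
  my <- sum(y) / n
  for (i in 1:n) {
    e <- p[i] - y[i]
    sse <- sse + e^2
    sae <- sae + abs(e)
    sape <- sape + abs(e) / abs(y[i])
    sst <- sst + (y[i] - my)^2
  }
  list(r2 = 1 - sse / sst, rmse = sqrt(sse / n), mae = sae / n,
       mape = sape / n * 100, rrmse = sqrt(sse / n) / my * 100)
}

# Partial correlation through the precision matrix of [x, y, controls].
oracle_partial_cor <- function(x, y, Z) {
  S <- stats::cov(cbind(x, y, Z))
  P <- solve(S)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Direct windowed SSIM evaluation with border-clipped uniform windows.
oracle_ssim <- function(x, y, win = 7L) {
  h <- nrow(x); w <- ncol(x)
  half <- (win - 1) %/% 2
  Lr <- diff(range(y)); if (Lr == 0) Lr <- 1
  C1 <- (0.01 * Lr)^2; C2 <- (0.03 * Lr)^2
  acc <- 0
  for (i in 1:h) for (j in 1:w) {
    ri <- max(1, i - half):min(h, i + half)
    ci <- max(1, j - half):min(w, j + half)
    xs <- as.vector(x[ri, ci]); ys <- as.vector(y[ri, ci])
    mx <- mean(xs); my <- mean(ys)
    vx <- mean(xs^2) - mx^2; vy <- mean(ys^2) - my^2
    cxy <- mean(xs * ys) - mx * my
    acc <- acc + ((2 * mx * my + C1) * (2 * cxy + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
  acc / (h * w)
}
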