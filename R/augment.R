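## CutMix augmentation for regression: rectangular region transplant
## between training patches with area-weighted label mixing.

#' CutMix two temporal samples
#'
#' Cuts an axis-aligned rectangle covering (approximately, up to pixel
#' rounding) `fraction` of the patch area at a uniformly random location
#' from the donor sample and pastes it at the same coordinates into the
#' base sample, using the same region across all L stage patches. The
#' mixed label is the area-weighted combination
#' `yc = (1 - lambda) * ya + lambda * yb`, where `lambda` is the realized
#' pixel fraction of the transplanted rectangle (so at the default 40%
#' area the base label keeps a 60% weight). The rectangle's aspect ratio
#' is drawn uniformly in [0.5, 2].
#'
#' @param sample_a base `temporal_sample` (label `ya`).
#' @param sample_b donor `temporal_sample` (label `yb`), same patch shape.
#' @param fraction target area fraction in [0, 1], default 0.40.
#' @param seed optional seed for the region draw.
#' @return a `temporal_sample` with mixed patches and label, plus fields
#'   `lambda`, `region` (r0, r1, c0, c1), `synthetic = TRUE` and
#'   `parent_points` (both parents' point IDs).
#' @export
cutmix <- function(sample_a, sample_b, fraction = 0.40, seed = NULL) {
  if (fraction < 0 || fraction > 1) stopf("fraction must be in [0, 1]")
  da <- dim(sample_a$patches[[1]]); db <- dim(sample_b$patches[[1]])
  if (!identical(da, db))
    stopf("patch shape mismatch: %s vs %s",
          paste(da, collapse = "x"), paste(db, collapse = "x"))
  h <- da[1]; w <- da[2]
  with_seed(seed, {
    target <- round(fraction * h * w)
    if (target == 0L) {
      region <- NULL
      lambda <- 0
    } else if (target == h * w) {
      region <- c(1L, h, 1L, w)
      lambda <- 1
    } else {
      ## candidate heights spanning aspect ratios in [0.5, 2]; take the
      ## height/width pair whose pixel area is nearest the target (ties
      ## resolved uniformly at random), so the realized area misses the
      ## request only by pixel quantization
      rhs <- seq.int(max(1L, ceiling(sqrt(target / 2))),
                     min(h, floor(sqrt(2 * target))))
      if (!length(rhs)) rhs <- max(1L, min(h, as.integer(round(sqrt(target)))))
      rws <- pmax(1L, pmin(w, as.integer(round(target / rhs))))
      err <- abs(rhs * rws - target)
      best <- which(err == min(err))
      pick <- best[sample.int(length(best), 1L)]
      rh <- rhs[pick]; rw <- rws[pick]
      r0 <- sample.int(h - rh + 1L, 1L)
      c0 <- sample.int(w - rw + 1L, 1L)
      region <- c(r0, r0 + rh - 1L, c0, c0 + rw - 1L)
      lambda <- (rh * rw) / (h * w)
    }
    out <- sample_a
    if (!is.null(region)) {
      for (t in seq_along(out$patches)) {
        if (is.null(out$patches[[t]]) || is.null(sample_b$patches[[t]])) next
        out$patches[[t]][region[1]:region[2], region[3]:region[4], ] <-
          sample_b$patches[[t]][region[1]:region[2], region[3]:region[4], ]
      }
    }
    out$lai <- (1 - lambda) * sample_a$lai + lambda * sample_b$lai
    out$lambda <- lambda
    out$region <- region
    out$synthetic <- TRUE
    out$parent_points <- unique(c(sample_a$parent_points,
                                  sample_b$parent_points))
    out$point_id <- NA_integer_
    out
  })
}

#' Mix two labels by area fraction
#'
#' The CutMix label rule in isolation: `yc = (1 - lambda) * ya + lambda * yb`.
#' @param ya,yb parent labels.
#' @param lambda donor area fraction in [0, 1].
#' @return the mixed label.
#' @export
cutmix_label <- function(ya, yb, lambda = 0.40) {
  if (lambda < 0 || lambda > 1) stopf("lambda must be in [0, 1]")
  (1 - lambda) * ya + lambda * yb
}

#' Expand a training set with CutMix samples
#'
#' Appends `n_aug` synthetic samples, each mixed from a uniformly drawn
#' ordered pair of distinct training samples. Originals are preserved and
#' every synthetic sample is tagged (`synthetic = TRUE`) and carries both
#' parents' point IDs, so the evaluation module can keep augmented samples
#' on the training side of any split. Augmentation is meant for training
#' data only; the test set stays untouched.
#'
#' @param train list of `temporal_sample` objects (length >= 2).
#' @param n_aug number of synthetic samples to append.
#' @param fraction CutMix area fraction (default 0.40).
#' @param seed seed for pair and region draws.
#' @return list of length `length(train) + n_aug`.
#' @export
augment_training_set <- function(train, n_aug, fraction = 0.40, seed = NULL) {
  if (n_aug == 0L) return(train)
  if (length(train) < 2L) stopf("need at least 2 training samples to mix")
  with_seed(seed, {
    m <- length(train)
    extra <- lapply(seq_len(n_aug), function(i) {
      ab <- sample.int(m, 2L)            # ordered pair of distinct samples
      cutmix(train[[ab[1]]], train[[ab[2]]], fraction = fraction)
    })
    c(train, extra)
  })
}
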