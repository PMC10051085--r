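# Paired geometric augmentation: flips, rotation and zoom, applied
# identically to the image and its mask. The image is resampled
# bilinearly, the mask with nearest-neighbour sampling so it stays
# binary; pixels mapped from outside the frame are filled with 0
# (image) and background (mask). Each transform fires with probability
# one half, with its magnitude drawn uniformly within the policy range.

#' Augmentation policy
#'
#' @param horizontal_flip,vertical_flip Enable the two mirror flips.
#' @param rotation_max_degrees Maximum absolute rotation angle; the
#'   drawn angle is uniform in `[-max, max]`. Must lie in `[0, 180]`.
#' @param zoom_range Maximum relative scale deviation in `[0, 1)`; the
#'   drawn scale is uniform in `[1 - z, 1 + z]`.
#' @param seed Integer used as the default draw seed in
#'   [augment_pair()].
#' @return An object of class `augmentation_policy`. The all-disabled
#'   policy is the identity transform.
#' @export
augmentation_policy <- function(horizontal_flip = TRUE, vertical_flip = TRUE,
                                rotation_max_degrees = 20, zoom_range = 0.1,
                                seed = 1L) {
  if (rotation_max_degrees < 0 || rotation_max_degrees > 180)
    stop("rotation_max_degrees must lie in [0, 180]")
  if (zoom_range < 0 || zoom_range >= 1)
    stop("zoom_range must lie in [0, 1)")
  structure(list(horizontal_flip = isTRUE(horizontal_flip),
                 vertical_flip = isTRUE(vertical_flip),
                 rotation_max_degrees = rotation_max_degrees,
                 zoom_range = zoom_range,
                 seed = as.integer(seed)),
            class = "augmentation_policy")
}

# Inverse-mapping affine resampler: output pixel p takes the value at
# source position center + R(-theta) (p - center) / scale. `filter` is
# "bilinear" (zero fill) or "nearest" (fill value `fill`).
affine_resample <- function(x, theta_deg, scale, filter = "bilinear", fill = 0) {
  d <- dim(x)
  h <- d[1L]; w <- d[2L]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- theta_deg * pi / 180
  gy <- rep(seq_len(h), times = w) - cy
  gx <- rep(seq_len(w), each = h) - cx
  sy <- cy + (cos(th) * gy - sin(th) * gx) / scale
  sx <- cx + (sin(th) * gy + cos(th) * gx) / scale
  nc <- if (length(d) == 3L) d[3L] else 1L
  if (length(d) == 2L) dim(x) <- c(h, w, 1L)
  out <- array(fill, c(h, w, nc))
  if (filter == "nearest") {
    ry <- round(sy); rx <- round(sx)
    ok <- ry >= 1 & ry <= h & rx >= 1 & rx <= w
    idx <- ry[ok] + (rx[ok] - 1) * h
    for (c in seq_len(nc)) {
      plane <- matrix(fill, h, w)
      src <- x[, , c]
      plane[ok] <- src[idx]
      out[, , c] <- plane
    }
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    gather <- function(src, yy, xx) {
      ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
      v <- numeric(length(yy))
      v[ok] <- src[yy[ok] + (xx[ok] - 1) * h]
      v
    }
    for (c in seq_len(nc)) {
      src <- x[, , c]
      v <- (1 - fy) * (1 - fx) * gather(src, y0, x0) +
           fy * (1 - fx) * gather(src, y0 + 1, x0) +
           (1 - fy) * fx * gather(src, y0, x0 + 1) +
           fy * fx * gather(src, y0 + 1, x0 + 1)
      out[, , c] <- matrix(v, h, w)
    }
  }
  if (length(d) == 2L) out[, , 1L] else out
}

#' Apply a random paired augmentation to a sample
#'
#' Draws the transform from the policy under `draw_seed` (so the same
#' triple of sample, policy and seed always yields the same output) and
#' applies it identically to image and mask. Flips are exact index
#' reversals; rotation and zoom resample on the fixed output grid, so
#' dimensions never change.
#'
#' @param sample An [image_sample()].
#' @param policy An [augmentation_policy()].
#' @param draw_seed Integer seed for this draw; defaults to the policy
#'   seed.
#' @return The augmented [image_sample()].
#' @export
augment_pair <- function(sample, policy, draw_seed = policy$seed) {
  stopifnot(inherits(sample, "image_sample"),
            inherits(policy, "augmentation_policy"))
  with_seed(draw_seed, {
    img <- sample$image
    msk <- sample$mask
    if (policy$horizontal_flip && stats::runif(1) < 0.5) {
      img <- img[, rev(seq_len(ncol(msk))), , drop = FALSE]
      msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
    }
    if (policy$vertical_flip && stats::runif(1) < 0.5) {
      img <- img[rev(seq_len(nrow(msk))), , , drop = FALSE]
      msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
    }
    theta <- 0; scale <- 1
    if (policy$rotation_max_degrees > 0 && stats::runif(1) < 0.5)
      theta <- stats::runif(1, -policy$rotation_max_degrees,
                            policy$rotation_max_degrees)
    if (policy$zoom_range > 0 && stats::runif(1) < 0.5)
      scale <- 1 + stats::runif(1, -policy$zoom_range, policy$zoom_range)
    if (theta != 0 || scale != 1) {
      img <- affine_resample(img, theta, scale, "bilinear", fill = 0)
      img[img < 0] <- 0; img[img > 1] <- 1
      msk <- affine_resample(msk, theta, scale, "nearest", fill = 0)
    }
    image_sample(img, msk, sample$id)
  })
}
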