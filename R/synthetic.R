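# Synthetic endoscopy-like scenes with exact ground-truth masks, so the
# whole pipeline is testable without downloading clinical data. A scene
# is a smoothly textured mucosa-toned background carrying one or more
# red-dominant lesion blobs; each blob is a radially perturbed ellipse
# (radius(theta) = base * (1 + irregularity * smooth_noise(theta)) with
# the smooth noise a low-order random trigonometric series), plus
# additive Gaussian pixel noise clipped to [0, 1]. The mask is 1 exactly
# on lesion pixels.

#' Synthetic scene specification
#'
#' Defaults emulate the look of capsule-endoscopy red-lesion frames:
#' pink-brown background, red-dominant lesions of diverse sizes.
#'
#' @param size Scene height and width in pixels.
#' @param n_lesions Maximum number of lesions; [generate_scene()] draws
#'   exactly this many, [generate_dataset()] varies the count per sample
#'   between 1 and this value.
#' @param radius_range Minimum and maximum base radius in pixels; the
#'   maximum perturbed radius must fit in half the scene.
#' @param lesion_color_mean,background_color_mean RGB means in `[0, 1]`.
#' @param boundary_irregularity Amplitude of the radial boundary
#'   perturbation (0 gives exact discs).
#' @param noise_sigma Standard deviation of the additive Gaussian pixel
#'   noise.
#' @param seed Integer seed making the scene deterministic.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(size = c(64L, 64L), n_lesions = 2L,
                       radius_range = c(4, 14),
                       lesion_color_mean = c(0.75, 0.15, 0.15),
                       background_color_mean = c(0.55, 0.35, 0.30),
                       boundary_irregularity = 0.3,
                       noise_sigma = 0.03,
                       seed = 1L) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 4L)) stop("size must be >= 4 pixels")
  if (n_lesions < 0L) stop("n_lesions must be >= 0")
  if (length(radius_range) != 2L || radius_range[1L] > radius_range[2L] ||
      radius_range[1L] <= 0)
    stop("radius_range must be positive and increasing")
  if (radius_range[2L] >= min(size) / 2)
    stop("maximum radius must be < min(size)/2")
  stopifnot(all(lesion_color_mean >= 0 & lesion_color_mean <= 1),
            all(background_color_mean >= 0 & background_color_mean <= 1),
            boundary_irregularity >= 0, noise_sigma >= 0)
  structure(list(size = size, n_lesions = as.integer(n_lesions),
                 radius_range = radius_range,
                 lesion_color_mean = lesion_color_mean,
                 background_color_mean = background_color_mean,
                 boundary_irregularity = boundary_irregularity,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "scene_spec")
}

# low-order random trigonometric series on [0, 2pi), bounded in [-1, 1]
smooth_angular_noise <- function() {
  k <- 1:4
  a <- stats::rnorm(4) / k
  b <- stats::rnorm(4) / k
  nrm <- sum(abs(a) + abs(b))
  if (nrm == 0) nrm <- 1
  function(theta) {
    s <- 0
    for (j in k) s <- s + a[j] * cos(j * theta) + b[j] * sin(j * theta)
    s / nrm
  }
}

#' Generate one synthetic lesion scene
#'
#' @param spec A [scene_spec()].
#' @param id Identifier for the resulting sample.
#' @return An [image_sample()] whose mask is 1 exactly on lesion pixels.
#' @export
generate_scene <- function(spec, id = sprintf("scene%06d", spec$seed)) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$size[1L]; w <- spec$size[2L]
  irr <- spec$boundary_irregularity
  margin <- spec$radius_range[2L] * (1 + irr) + 1
  if (2 * margin >= min(h, w))
    stop("lesion cannot fit: radius and irregularity too large for the scene")
  with_seed(spec$seed, {
    # smooth background texture: low-resolution noise field upsampled
    lo <- max(4L, min(h, w) %/% 8L)
    Ah <- interp_matrix(lo, h); Aw <- interp_matrix(lo, w)
    img <- array(0, c(h, w, 3L))
    for (c in 1:3) {
      field <- array(stats::rnorm(lo * lo, sd = 0.06), c(lo, lo, 1L, 1L))
      img[, , c] <- spec$background_color_mean[c] +
        nn_resize_lin(field, Ah, Aw)[, , 1L, 1L]
    }
    mask <- matrix(0, h, w)
    gy <- rep(seq_len(h), times = w)
    gx <- rep(seq_len(w), each = h)
    if (spec$n_lesions > 0) {
      for (k in seq_len(spec$n_lesions)) {
        r <- stats::runif(1, spec$radius_range[1L], spec$radius_range[2L])
        m <- r * (1 + irr) + 1
        cy <- stats::runif(1, m, h - m)
        cx <- stats::runif(1, m, w - m)
        asp <- 1 + stats::runif(2, -1, 1) * min(0.25, irr)
        phi <- stats::runif(1, 0, pi)
        sn <- smooth_angular_noise()
        col <- pmin(1, pmax(0, spec$lesion_color_mean + stats::rnorm(3, sd = 0.04)))
        dy <- gy - cy; dx <- gx - cx
        rho <- sqrt(dy^2 + dx^2)
        theta <- atan2(dy, dx)
        # radially perturbed ellipse boundary
        re <- r / sqrt((cos(theta - phi) / asp[1L])^2 +
                       (sin(theta - phi) / asp[2L])^2)
        inside <- rho <= re * (1 + irr * sn(theta))
        mask[inside] <- 1
        # gentle interior shading toward the rim
        shade <- 1 - 0.25 * pmin(1, rho[inside] / max(re[inside], 1e-9))
        for (c in 1:3) {
          plane <- img[, , c]
          plane[inside] <- col[c] * (0.85 + 0.15 * shade)
          img[, , c] <- plane
        }
      }
    }
    if (spec$noise_sigma > 0)
      img <- img + array(stats::rnorm(length(img), sd = spec$noise_sigma), dim(img))
    img[img < 0] <- 0; img[img > 1] <- 1
    image_sample(img, mask, id)
  })
}

#' Generate a synthetic dataset
#'
#' Per-sample seeds are derived deterministically from the master seed;
#' the lesion count varies uniformly in `1..spec$n_lesions` (or stays 0
#' if the spec has no lesions) and sizes vary within `radius_range`.
#'
#' @param spec A [scene_spec()] template.
#' @param n_samples Number of scenes.
#' @param seed Master seed; two calls with the same seed produce
#'   elementwise identical datasets.
#' @return List of [image_sample()] objects with distinct identifiers.
#' @export
generate_dataset <- function(spec, n_samples, seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  if (n_samples <= 0L) stop("n_samples must be positive")
  out <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    si <- derive_seed(seed, i)
    s <- spec
    s$seed <- as.integer(si %% 2147483629)
    if (spec$n_lesions > 0)
      s$n_lesions <- with_seed(s$seed + 1, sample.int(spec$n_lesions, 1L))
    out[[i]] <- generate_scene(s, id = sprintf("scene%05d", i))
  }
  out
}

#' Write a synthetic dataset to disk in the images/masks layout
#'
#' @param samples List of [image_sample()] objects.
#' @param dir Output directory; `images/` and `masks/` are created.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    write_image(s$image, file.path(dir, "images", paste0(s$id, ".png")))
    write_mask(s$mask, file.path(dir, "masks", paste0(s$id, ".png")))
  }
  invisible(dir)
}
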