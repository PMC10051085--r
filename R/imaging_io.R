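# Reading, writing, resizing, normalizing and splitting paired
# image/mask data in the `images/` + `masks/` directory layout used by
# the public polyp-segmentation datasets (matching filename stems).
# File decoding goes through EBImage; geometric resampling uses the
# package's own separable kernels so that image resizing and in-network
# interpolation share one numerical convention and masks stay binary.

#' Construct and validate an image/mask sample
#'
#' @param image H x W x 3 numeric array with values in `[0, 1]` (an
#'   H x W matrix or single-channel array is replicated to 3 channels).
#' @param mask H x W binary matrix (values 0/1).
#' @param id Identifier string, conventionally the source filename stem.
#' @return An object of class `image_sample`.
#' @export
image_sample <- function(image, mask, id = "sample") {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (length(d) != 3L) stop("image must be an H x W x C array")
  if (d[3L] == 1L) image <- array(rep(image, 3L), c(d[1L], d[2L], 3L))
  if (dim(image)[3L] > 3L) image <- image[, , 1:3, drop = FALSE]
  mask <- as.matrix(mask)
  if (!identical(dim(image)[1:2], dim(mask)))
    stop("image (", d[1L], "x", d[2L], ") and mask (", nrow(mask), "x",
         ncol(mask), ") dimensions differ")
  if (min(image) < 0 || max(image) > 1)
    stop("image values must lie in [0, 1]; call normalize_image() first")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
  structure(list(image = image, mask = mask * 1, id = as.character(id)),
            class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  d <- dim(x$image)
  cat("<image_sample> ", x$id, ": ", d[1L], "x", d[2L], "x", d[3L],
      ", foreground ", round(100 * mean(x$mask), 1), "%\n", sep = "")
  invisible(x)
}

read_image_array <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- try(EBImage::readImage(path), silent = TRUE)
  if (inherits(img, "try-error")) stop("cannot decode image: ", path)
  a <- EBImage::imageData(img)          # (W, H) or (W, H, C), values [0,1]
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  aperm(a[, , , drop = FALSE], c(2L, 1L, 3L))   # -> (H, W, C)
}

#' Load an image/mask pair from files
#'
#' The mask is collapsed to one channel if needed and binarized at the
#' midpoint of the source bit depth (> 127 on 8-bit masks becomes 1).
#' Grayscale images are replicated to 3 channels. Pixel values arrive
#' already scaled to `[0, 1]` by the decoder.
#'
#' @param image_path,mask_path Paths to a PNG or JPEG image and its
#'   single-channel mask.
#' @param id Identifier; defaults to the image filename stem.
#' @return An [image_sample()].
#' @export
load_pair <- function(image_path, mask_path,
                      id = tools::file_path_sans_ext(basename(image_path))) {
  img <- read_image_array(image_path)
  msk <- read_image_array(mask_path)
  msk <- if (dim(msk)[3L] > 1L) apply(msk, c(1, 2), mean) else msk[, , 1L]
  msk <- (msk > 0.5) * 1                # midpoint of the scaled bit depth
  if (!identical(dim(img)[1:2], dim(msk)))
    stop("image/mask dimension mismatch for ", id, ": ",
         paste(dim(img)[1:2], collapse = "x"), " vs ",
         paste(dim(msk), collapse = "x"))
  image_sample(img, msk, id)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0, so that
#' [load_pair()] recovers the identical binary mask.
#'
#' @param mask H x W binary matrix.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path, type = "png")
  invisible(path)
}

#' Write an RGB image as an 8-bit PNG
#' @param image H x W x 3 array in `[0, 1]`.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  a <- aperm(image, c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path, type = "png")
  invisible(path)
}

#' Rescale 8-bit pixel values to the unit interval
#'
#' Divides by 255, the largest 8-bit pixel value, mapping 0 to 0 and 255
#' to 1.
#'
#' @param raw_image Numeric array with integer values in `[0, 255]`.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
normalize_image <- function(raw_image) {
  if (min(raw_image) < 0 || max(raw_image) > 255)
    stop("pixel values must lie in [0, 255]")
  raw_image / 255
}

#' Resize a sample to a target resolution
#'
#' The image is resized with a separable bilinear kernel; the mask with
#' nearest-neighbour sampling so it remains binary.
#'
#' @param sample An [image_sample()].
#' @param target Integer vector `(H, W)`.
#' @return The resized [image_sample()].
#' @export
resize_sample <- function(sample, target) {
  target <- as.integer(target)
  if (length(target) != 2L || any(target < 1L))
    stop("target must be two positive integers")
  d <- dim(sample$image)
  if (all(d[1:2] == target)) return(sample)
  Ah <- interp_matrix(d[1L], target[1L])
  Aw <- interp_matrix(d[2L], target[2L])
  x <- array(sample$image, c(d[1L], d[2L], d[3L], 1L))
  img <- nn_resize_lin(x, Ah, Aw)
  img <- array(img, c(target, d[3L]))
  img[img < 0] <- 0; img[img > 1] <- 1
  msk <- resize_nearest_2d(sample$mask, target[1L], target[2L])
  image_sample(img, msk, sample$id)
}

#' Train/validation/test split specification
#'
#' @param train,validation,test Fractions in `[0, 1]` summing to 1.
#'   Default 60/20/20, the protocol used for model development; an 80/20
#'   split is expressed as `dataset_split(0.8, 0, 0.2)`.
#' @param seed Integer controlling the random assignment.
#' @return An object of class `dataset_split`.
#' @export
dataset_split <- function(train = 0.6, validation = 0.2, test = 0.2, seed = 1L) {
  f <- c(train, validation, test)
  if (any(f < 0) || any(f > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(list(train = train, validation = validation, test = test,
                 seed = as.integer(seed)),
            class = "dataset_split")
}

#' Randomly partition samples into train/validation/test sets
#'
#' Validation and test sizes are `round(n * fraction)`; the remainder
#' goes to the training set. The assignment is a seeded random
#' permutation, so the same seed always yields the same partition and
#' no sample appears in two sets.
#'
#' @param samples List of samples (any type).
#' @param split A [dataset_split()].
#' @return List with elements `train`, `validation`, `test`.
#' @export
split_dataset <- function(samples, split = dataset_split()) {
  stopifnot(inherits(split, "dataset_split"))
  n <- length(samples)
  if (n < 3L) stop("need at least 3 samples to split")
  n_val <- round(n * split$validation)
  n_test <- round(n * split$test)
  n_train <- n - n_val - n_test
  idx <- with_seed(split$seed, sample.int(n))
  list(train = samples[idx[seq_len(n_train)]],
       validation = samples[idx[n_train + seq_len(n_val)]],
       test = samples[idx[n_train + n_val + seq_len(n_test)]])
}

#' Load a dataset directory of paired images and masks
#'
#' Expects `images/` and `masks/` subdirectories with matching filename
#' stems (the Kvasir-SEG convention).
#'
#' @param dir Dataset root directory.
#' @param target Optional `(H, W)` to resize every sample to.
#' @return List of [image_sample()] objects, ordered by stem.
#' @export
load_dataset <- function(dir, target = NULL) {
  img_dir <- file.path(dir, "images")
  msk_dir <- file.path(dir, "masks")
  if (!dir.exists(img_dir) || !dir.exists(msk_dir))
    stop("expected images/ and masks/ under ", dir)
  imgs <- list.files(img_dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE)
  if (length(imgs) == 0L) stop("no images found in ", img_dir)
  imgs <- imgs[order(tools::file_path_sans_ext(imgs))]
  masks <- list.files(msk_dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE)
  mask_stem <- tools::file_path_sans_ext(masks)
  out <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    stem <- tools::file_path_sans_ext(imgs[i])
    j <- match(stem, mask_stem)
    if (is.na(j)) stop("no mask found for image stem '", stem, "'")
    s <- load_pair(file.path(img_dir, imgs[i]), file.path(msk_dir, masks[j]))
    if (!is.null(target)) s <- resize_sample(s, target)
    out[[i]] <- s
  }
  out
}
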