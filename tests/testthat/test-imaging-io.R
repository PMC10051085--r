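# Image/mask input-output, normalization, resizing and splitting.

test_that("write_mask then load_pair recovers the binary mask bit-exactly", {
  set.seed(10)
  msk <- random_mask(23, 17, 0.4)
  img <- array(runif(23 * 17 * 3), c(23, 17, 3))
  td <- withr::local_tempdir()
  ip <- file.path(td, "img.png")
  mp <- file.path(td, "msk.png")
  write_image(img, ip)
  write_mask(msk, mp)
  s <- load_pair(ip, mp)
  expect_identical(s$mask, msk * 1)
  expect_equal(dim(s$image), c(23, 17, 3))
  expect_true(all(s$image >= 0 & s$image <= 1))
  expect_equal(s$id, "img")
})

test_that("mask binarization thresholds at the bit-depth midpoint", {
  td <- withr::local_tempdir()
  vals <- c(0, 100, 127, 128, 200, 255) / 255
  m <- matrix(vals, 2, 3)
  EBImage::writeImage(EBImage::Image(t(m)), file.path(td, "m.png"))
  img <- array(0.5, c(2, 3, 3))
  write_image(img, file.path(td, "i.png"))
  s <- load_pair(file.path(td, "i.png"), file.path(td, "m.png"))
  expect_equal(s$mask, matrix((vals * 255 > 127) * 1, 2, 3))
})

test_that("grayscale images are replicated to three identical channels", {
  td <- withr::local_tempdir()
  g <- matrix(runif(12), 4, 3)
  EBImage::writeImage(EBImage::Image(t(g)), file.path(td, "g.png"))
  write_mask(random_mask(4, 3), file.path(td, "m.png"))
  s <- load_pair(file.path(td, "g.png"), file.path(td, "m.png"))
  expect_equal(s$image[, , 1], s$image[, , 2])
  expect_equal(s$image[, , 2], s$image[, , 3])
})

test_that("image/mask dimension mismatch raises an error", {
  td <- withr::local_tempdir()
  write_image(array(0.5, c(10, 8, 3)), file.path(td, "i.png"))
  write_mask(random_mask(8, 10), file.path(td, "m.png"))
  expect_error(load_pair(file.path(td, "i.png"), file.path(td, "m.png")),
               "mismatch")
  expect_error(image_sample(array(0.5, c(5, 4, 3)), random_mask(4, 5)),
               "differ")
})

test_that("normalize_image divides by 255 and preserves order", {
  expect_equal(normalize_image(array(255, c(2, 2))), array(1, c(2, 2)))
  expect_equal(normalize_image(array(0, c(2, 2))), array(0, c(2, 2)))
  expect_equal(normalize_image(128), 128 / 255)
  expect_error(normalize_image(c(-1, 5)), "\\[0, 255\\]")
  expect_error(normalize_image(256), "\\[0, 255\\]")
  set.seed(11)
  a <- sample(0:255, 100, replace = TRUE)
  b <- sample(0:255, 100, replace = TRUE)
  n <- normalize_image(a) - normalize_image(b)
  expect_true(all(sign(n) == sign(a - b)))
})

test_that("resize_sample maps 574x500 to 128x128 and keeps masks binary", {
  set.seed(12)
  s <- image_sample(array(runif(574 * 500 * 3), c(574, 500, 3)),
                    random_mask(574, 500, 0.2), "big")
  r <- resize_sample(s, c(128, 128))
  expect_equal(dim(r$image), c(128, 128, 3))
  expect_equal(dim(r$mask), c(128, 128))
  expect_true(all(r$mask %in% c(0, 1)))
  expect_true(all(r$image >= 0 & r$image <= 1))
  # identity resize returns the sample unchanged
  small <- random_samples(1)[[1]]
  expect_identical(resize_sample(small, c(16, 16)), small)
  expect_error(resize_sample(small, c(0, 4)), "positive")
})

test_that("split_dataset produces the documented partition sizes", {
  samples <- as.list(seq_len(1000))
  p <- split_dataset(samples, dataset_split(0.6, 0.2, 0.2, seed = 3))
  expect_equal(lengths(p), c(train = 600, validation = 200, test = 200))
  p2 <- split_dataset(samples, dataset_split(0.8, 0, 0.2, seed = 3))
  expect_equal(lengths(p2), c(train = 800, validation = 0, test = 200))
  # same seed twice: identical partitions
  p3 <- split_dataset(samples, dataset_split(0.6, 0.2, 0.2, seed = 3))
  expect_identical(p, p3)
  expect_error(split_dataset(as.list(1:2), dataset_split()), "at least 3")
  expect_error(dataset_split(0.5, 0.2, 0.2), "sum to 1")
})

test_that("split_dataset partitions: union is the input, intersections empty", {
  set.seed(13)
  for (trial in seq_len(1000)) {
    n <- sample(3:50, 1)
    p <- split_dataset(as.list(seq_len(n)),
                       dataset_split(seed = sample.int(1e6, 1)))
    ids <- c(unlist(p$train), unlist(p$validation), unlist(p$test))
    expect_identical(sort(ids), seq_len(n))   # implies no duplicates
  }
})

test_that("a written dataset directory loads back through load_dataset", {
  td <- withr::local_tempdir()
  samples <- generate_dataset(scene_spec(size = c(24, 24), radius_range = c(3, 6)),
                              4, seed = 5)
  write_dataset(samples, td)
  back <- load_dataset(td)
  expect_length(back, 4)
  for (i in seq_len(4))
    expect_identical(back[[i]]$mask, samples[[i]]$mask)
})
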