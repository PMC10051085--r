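# Evaluation metrics against the brute-force per-pixel oracle and the
# algebraic identities linking Dice and Jaccard.

test_that("confusion counts match a per-pixel loop on random pairs", {
  set.seed(50)
  for (trial in 1:20) {
    pred <- random_mask(16, 16); truth <- random_mask(16, 16)
    cc <- confusion_counts(pred, truth)
    oc <- oracle_confusion(pred, truth)
    expect_identical(unclass(cc)[c("tp", "tn", "fp", "fn")],
                     lapply(oc[c("tp", "tn", "fp", "fn")], as.integer))
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 256)
  }
})

test_that("perfect and inverted predictions give the expected counts", {
  truth <- matrix(0, 10, 10); truth[1:5, 1:6] <- 1   # 30 foreground pixels
  cc <- confusion_counts(truth, truth)
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 30L, tn = 70L, fp = 0L, fn = 0L))
  expect_equal(pixel_accuracy(cc), 1)
  inv <- confusion_counts(1 - truth, truth)
  expect_equal(inv$tp, 0L)
  expect_equal(inv$tn, 0L)
  expect_equal(pixel_accuracy(inv), 0)
})

test_that("dice and jaccard reproduce hand-computed overlap examples", {
  # |A| = 6, |B| = 4, |A n B| = 3 on a 4x4 grid
  a <- matrix(0, 4, 4); a[1, 1:4] <- 1; a[2, 1:2] <- 1
  b <- matrix(0, 4, 4); b[1, 2:4] <- 1; b[3, 1] <- 1
  expect_equal(sum(a), 6); expect_equal(sum(b), 4)
  expect_equal(sum(a * b), 3)
  expect_equal(dice_coefficient(a, b), 0.6)           # 2*3 / (6+4)
  expect_equal(jaccard_index(a, b), 3 / 7)            # 3 / (6+4-3)
  expect_equal(pixel_accuracy(confusion_counts(a, b)), (3 + 9) / 16)
})

test_that("identical masks score 1 and disjoint masks score 0", {
  m <- random_mask(8, 8, 0.4)
  if (sum(m) == 0) m[1, 1] <- 1
  expect_equal(dice_coefficient(m, m), 1)
  expect_equal(jaccard_index(m, m), 1)
  d <- matrix(0, 8, 8); d[1, 1] <- 1
  e <- matrix(0, 8, 8); e[8, 8] <- 1
  expect_equal(dice_coefficient(d, e), 0)
  expect_equal(jaccard_index(d, e), 0)
})

test_that("empty versus empty masks are scored as perfect agreement", {
  z <- matrix(0, 5, 5)
  expect_equal(dice_coefficient(z, z), 1)
  expect_equal(jaccard_index(z, z), 1)
})

test_that("accuracy example: tp 3, tn 90, fp 3, fn 4 gives 0.93", {
  cc <- structure(list(tp = 3, tn = 90, fp = 3, fn = 4),
                  class = "confusion_counts")
  expect_equal(pixel_accuracy(cc), 0.93)
})

test_that("metrics are symmetric, satisfy D = 2J/(1+J), and J <= D", {
  set.seed(51)
  for (trial in 1:100) {
    a <- random_mask(12, 12, runif(1, 0.1, 0.9))
    b <- random_mask(12, 12, runif(1, 0.1, 0.9))
    d <- dice_coefficient(a, b); j <- jaccard_index(a, b)
    expect_equal(dice_coefficient(b, a), d)
    expect_equal(jaccard_index(b, a), j)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_lte(j, d)
  }
})

test_that("non-binary or mismatched masks are rejected", {
  expect_error(dice_coefficient(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
  expect_error(jaccard_index(matrix(0, 2, 2), matrix(0, 3, 2)), "differ")
  expect_error(confusion_counts(matrix(2, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("evaluate_dataset equals an independent per-sample recomputation", {
  set.seed(52)
  m <- tiny_model("unet", c(16, 16), depth = 2)
  samples <- random_samples(10)
  rep <- evaluate_dataset(m, samples, threshold = 0.5)
  dices <- accs <- jacs <- numeric(10)
  for (i in 1:10) {
    pred <- predict_mask(m, samples[[i]]$image, 0.5)
    dices[i] <- oracle_dice(pred, samples[[i]]$mask)
    jacs[i] <- oracle_jaccard(pred, samples[[i]]$mask)
    oc <- oracle_confusion(pred, samples[[i]]$mask)
    accs[i] <- (oc$tp + oc$tn) / 256
  }
  expect_equal(rep$dice, mean(dices), tolerance = 1e-12)
  expect_equal(rep$jaccard, mean(jacs), tolerance = 1e-12)
  expect_equal(rep$accuracy, mean(accs), tolerance = 1e-12)
  expect_equal(rep$n_images, 10)
  # pooled identity: dice = 2J/(1+J) on pooled counts
  expect_equal(rep$pooled$dice,
               2 * rep$pooled$jaccard / (1 + rep$pooled$jaccard),
               tolerance = 1e-9)
})

test_that("metrics report writes parseable JSON and a one-row CSV", {
  set.seed(53)
  m <- tiny_model("unet", c(16, 16), depth = 2)
  rep <- evaluate_dataset(m, random_samples(3))
  td <- withr::local_tempdir()
  jp <- file.path(td, "r.json"); cp <- file.path(td, "r.csv")
  write_metrics_report(rep, jp, cp)
  j <- jsonlite::read_json(jp)
  expect_setequal(names(j), c("accuracy", "dice", "jaccard", "tp", "tn",
                              "fp", "fn", "n_images", "pooled"))
  csv <- read.csv(cp)
  expect_equal(nrow(csv), 1)
  expect_equal(csv$dice, rep$dice, tolerance = 1e-12)
})
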