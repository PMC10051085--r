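# Training protocol: loss arithmetic, optimizer behaviour, early
# stopping, reproducibility and checkpointing.

tiny_train_setup <- function(n = 8, h = 16, seed = 60) {
  samples <- generate_dataset(
    scene_spec(size = c(h, h), radius_range = c(2, 4), n_lesions = 1),
    n, seed = seed)
  split_dataset(samples, dataset_split(0.5, 0.25, 0.25, seed = seed))
}

quick_config <- function(...) {
  defaults <- list(batch_size = 4L, epochs = 3L, early_stop_patience = 10L,
                   seed = 3L, augmentation = NULL)
  do.call(train_config, utils::modifyList(defaults, list(...)))
}

test_that("binary cross-entropy matches hand-computed values", {
  # maximum-entropy prediction scores log 2 for any mask
  p <- array(0.5, c(4, 4))
  expect_equal(bce_loss(p, random_mask(4, 4)), log(2), tolerance = 1e-12)
  # 2x2 worked example
  p2 <- array(c(0.9, 0.1, 0.8, 0.2), c(2, 2))
  y2 <- array(c(1, 0, 1, 0), c(2, 2))
  expect_equal(bce_loss(p2, y2),
               mean(-c(log(0.9), log(0.9), log(0.8), log(0.8))),
               tolerance = 1e-12)
  # perfect-prediction limit: clamped, loss near 0
  expect_lt(bce_loss(y2, y2), 1e-5)
  expect_error(bce_loss(array(0.5, c(2, 2)), array(0, c(3, 3))), "differ")
})

test_that("learning rate zero leaves parameters untouched, loss constant", {
  set.seed(61)
  parts <- tiny_train_setup()
  m <- tiny_model("attresunet", c(16, 16), depth = 2, base_filters = 2)
  w0 <- m$weights
  fit <- train_segnet(m, parts$train, parts$validation,
                      quick_config(learning_rate = 0, epochs = 3))
  expect_identical(fit$model$weights, w0)
  expect_equal(diff(range(fit$history$val_loss)), 0, tolerance = 1e-12)
})

test_that("early stopping halts after patience non-improving epochs", {
  set.seed(62)
  parts <- tiny_train_setup()
  m <- tiny_model("attresunet", c(16, 16), depth = 2, base_filters = 2)
  # lr = 0 makes validation loss exactly constant: epoch 1 is the best,
  # every later epoch counts toward patience
  fit <- train_segnet(m, parts$train, parts$validation,
                      quick_config(learning_rate = 0, epochs = 10,
                                   early_stop_patience = 1))
  expect_equal(nrow(fit$history), 2)
  expect_equal(fit$best_epoch, 1)
  fit3 <- train_segnet(m, parts$train, parts$validation,
                       quick_config(learning_rate = 0, epochs = 10,
                                    early_stop_patience = 3))
  expect_equal(nrow(fit3$history), 4)
})

test_that("the restored model attains the best recorded validation loss", {
  set.seed(63)
  parts <- tiny_train_setup(n = 10)
  m <- tiny_model("attresunet", c(16, 16), depth = 2, base_filters = 2)
  fit <- train_segnet(m, parts$train, parts$validation,
                      quick_config(epochs = 5, learning_rate = 3e-3))
  v <- lesionseg:::validate_model(fit$model, parts$validation, 4L, "bce")
  expect_equal(v$loss, min(fit$history$val_loss), tolerance = 1e-10)
  expect_lte(min(fit$history$val_loss[seq_len(fit$best_epoch)]),
             min(fit$history$val_loss))
})

test_that("identical seeds and configs reproduce the history exactly", {
  parts <- tiny_train_setup()
  cfg <- quick_config(epochs = 2, augmentation = augmentation_policy())
  run <- function() {
    set.seed(cfg$seed)
    m <- build_model(model_config("attresunet", input_size = c(16, 16),
                                  depth = 2, base_filters = 2))
    train_segnet(m, parts$train, parts$validation, cfg)$history
  }
  expect_identical(run(), run())
})

test_that("training loss decreases when overfitting one repeated batch", {
  set.seed(64)
  samples <- generate_dataset(
    scene_spec(size = c(16, 16), radius_range = c(2, 4), n_lesions = 1),
    4, seed = 9)
  m <- tiny_model("attresunet", c(16, 16), depth = 2, base_filters = 2)
  fit <- train_segnet(m, samples, samples,
                      quick_config(batch_size = 4L, epochs = 5L))
  expect_lt(fit$history$train_loss[5], fit$history$train_loss[1])
})

test_that("checkpoints round-trip bit-identically and validate configs", {
  set.seed(65)
  m <- tiny_model("attresunet", c(16, 16), depth = 2, base_filters = 2)
  probe <- array(runif(16 * 16 * 3), c(16, 16, 3))
  td <- withr::local_tempdir()
  ck <- file.path(td, "model.rds")
  checkpoint_save(m, ck)
  m2 <- checkpoint_load(ck)
  expect_identical(forward_model(m2, probe), forward_model(m, probe))
  expect_equal(n_parameters(m2), n_parameters(m))
  # matching config accepted, mismatched rejected
  good <- model_config("attresunet", input_size = c(16, 16), depth = 2,
                       base_filters = 2)
  expect_s3_class(checkpoint_load(ck, good), "segnet_model")
  bad <- model_config("unet", input_size = c(16, 16), depth = 2,
                      base_filters = 2)
  expect_error(checkpoint_load(ck, bad), "does not match")
  expect_error(checkpoint_load(file.path(td, "absent.rds")), "not found")
})

test_that("the segnet fitting interface returns a usable classed object", {
  set.seed(66)
  parts <- tiny_train_setup(n = 8)
  fit <- segnet(parts$train, parts$validation, architecture = "attresunet",
                depth = 2, base_filters = 2,
                config = quick_config(epochs = 2))
  expect_s3_class(fit, "segnet")
  expect_equal(nrow(fit$history), 2)
  pr <- predict(fit, parts$test[[1]]$image)
  expect_equal(dim(pr), c(16, 16, 1))
  mk <- predict(fit, parts$test[[1]]$image, type = "mask")
  expect_true(all(mk %in% c(0, 1)))
  expect_output(print(fit), "attresunet")
  expect_output(summary(fit), "Blocks")
  expect_type(coef(fit), "list")
})
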