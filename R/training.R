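# Training protocol: minibatch Adam on binary cross-entropy (Dice loss
# available as an option), seeded shuffling, on-the-fly augmentation of
# training batches only, per-epoch validation, and early stopping on
# validation loss with best-weight restoration.

#' Training configuration
#'
#' Defaults follow the method's stated protocol: batch size 40, up to 50
#' epochs, Adam with beta1 = 0.9 and beta2 = 0.99 (as stated; note the
#' more common default is 0.999), and early stopping. The learning rate
#' and patience are not stated by the protocol; the conventional Adam
#' rate 1e-3 and patience 10 are used.
#'
#' @param batch_size Minibatch size.
#' @param epochs Maximum number of epochs.
#' @param learning_rate Adam step size. A rate of exactly 0 makes
#'   training a strict no-op: neither weights nor batch-norm running
#'   statistics change.
#' @param beta1,beta2 Adam moment decay rates, each in `(0, 1)`.
#' @param early_stop_patience Number of consecutive epochs without
#'   validation-loss improvement after which training halts.
#' @param loss `"bce"` (binary cross-entropy, default) or `"dice"`
#'   (soft Dice loss).
#' @param seed Integer seed controlling weight initialization order,
#'   shuffling and augmentation draws.
#' @param augmentation An [augmentation_policy()], or `NULL` to train
#'   without augmentation. Never applied to validation data.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 40L, epochs = 50L,
                         learning_rate = 1e-3,
                         beta1 = 0.9, beta2 = 0.99,
                         early_stop_patience = 10L,
                         loss = c("bce", "dice"),
                         seed = 1L,
                         augmentation = augmentation_policy()) {
  loss <- match.arg(loss)
  if (batch_size < 1L || epochs < 1L || early_stop_patience < 1L)
    stop("batch_size, epochs and early_stop_patience must be >= 1")
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1)
    stop("Adam betas must lie in (0, 1)")
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (!is.null(augmentation)) stopifnot(inherits(augmentation, "augmentation_policy"))
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2,
                 early_stop_patience = as.integer(early_stop_patience),
                 loss = loss, seed = as.integer(seed),
                 augmentation = augmentation),
            class = "train_config")
}

#' Mean binary cross-entropy over pixels
#'
#' `-mean(y log p + (1 - y) log(1 - p))`, with probabilities clamped to
#' `[1e-7, 1 - 1e-7]` for numerical safety. A maximally uncertain
#' prediction (p = 0.5 everywhere) scores `log(2)`.
#'
#' @param prob Array of predicted probabilities in `(0, 1)`.
#' @param mask Binary array of the same dimensions.
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(prob, mask) {
  if (!identical(dim(prob), dim(mask)) &&
      !identical(length(prob), length(mask)))
    stop("probability map and mask dimensions differ")
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  -mean(mask * log(p) + (1 - mask) * log(1 - p))
}

#' Soft Dice loss
#'
#' `1 - (2 sum(p y) + eps) / (sum(p) + sum(y) + eps)` with `eps = 1`.
#' @inheritParams bce_loss
#' @return Loss in `[0, 1]`.
#' @export
dice_loss <- function(prob, mask) {
  eps <- 1
  1 - (2 * sum(prob * mask) + eps) / (sum(prob) + sum(mask) + eps)
}

# gradient of the selected loss with respect to the pre-sigmoid logits
loss_grad_logits <- function(loss, p, y) {
  if (loss == "bce") {
    (p - y) / length(p)
  } else {
    eps <- 1
    num <- 2 * sum(p * y) + eps
    den <- sum(p) + sum(y) + eps
    dldp <- -(2 * y * den - num) / den^2
    dldp * p * (1 - p)
  }
}

# ---- Adam over the nested weight tree ----

adam_state <- function() new.env(parent = emptyenv())

adam_step <- function(weights, grads, state, lr, b1, b2, eps = 1e-8) {
  if (is.null(state$t)) {
    state$t <- 0L
    state$m <- list()
    state$v <- list()
  }
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  k <- 0L
  upd <- function(w, g) {
    if (is.list(w)) {
      nm <- names(w)
      for (i in seq_along(w)) {
        gi <- if (is.null(nm) || !nzchar(nm[i])) g[[i]] else g[[nm[i]]]
        w[[i]] <- upd(w[[i]], gi)
      }
      w
    } else {
      k <<- k + 1L
      if (length(state$m) < k) {
        state$m[[k]] <- 0 * w
        state$v[[k]] <- 0 * w
      }
      state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
      state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g * g
      w - lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
    }
  }
  upd(weights, grads)
}

stack_samples <- function(samples) {
  d <- dim(samples[[1L]]$image)
  n <- length(samples)
  x <- array(0, c(d[1L], d[2L], d[3L], n))
  y <- array(0, c(d[1L], d[2L], 1L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- samples[[i]]$image
    y[, , 1L, i] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

# inference-mode loss/accuracy/dice over a sample list, in minibatches
validate_model <- function(model, samples, batch_size, loss) {
  n <- length(samples)
  loss_sum <- 0; acc_sum <- 0; npix <- 0
  dices <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    b <- stack_samples(samples[i:j])
    p <- model_forward(model, b$x, training = FALSE)$p
    lf <- if (loss == "bce") bce_loss else dice_loss
    loss_sum <- loss_sum + lf(p, b$y) * length(p)
    pred <- (p >= 0.5) * 1
    acc_sum <- acc_sum + sum(pred == b$y)
    npix <- npix + length(p)
    for (k in i:j)
      dices[k] <- dice_coefficient(pred[, , 1L, k - i + 1L], samples[[k]]$mask)
    i <- j + 1L
  }
  list(loss = loss_sum / npix, accuracy = acc_sum / npix, dice = mean(dices))
}

#' Train a segmentation model
#'
#' Runs minibatch Adam for up to `config$epochs` epochs with seeded
#' shuffling, applying the augmentation policy to training batches only.
#' After every epoch the validation loss, accuracy and mean Dice are
#' recorded; training halts early once the validation loss has not
#' improved for `early_stop_patience` consecutive epochs, and the
#' returned model carries the weights of the best-validation-loss epoch.
#'
#' @param model A [build_model()] model.
#' @param train_samples,val_samples Non-empty lists of [image_sample()]
#'   objects at the model input size.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `model` (trained `segnet_model`), `history` (data
#'   frame: epoch, train_loss, train_acc, val_loss, val_acc, val_dice),
#'   and `best_epoch`.
#' @export
train_segnet <- function(model, train_samples, val_samples, config,
                         verbose = FALSE) {
  stopifnot(inherits(model, "segnet_model"), inherits(config, "train_config"))
  if (length(train_samples) == 0L || length(val_samples) == 0L)
    stop("training and validation sets must be non-empty")
  d <- dim(train_samples[[1L]]$image)
  if (!all(d[1:2] == model$config$input_size))
    stop("sample size ", d[1L], "x", d[2L], " does not match model input")

  set.seed(config$seed)
  state <- adam_state()
  history <- vector("list", config$epochs)
  best <- list(loss = Inf, weights = model$weights, buffers = model$buffers,
               epoch = 0L)
  wait <- 0L
  n <- length(train_samples)

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    loss_sum <- 0; acc_sum <- 0; npix <- 0
    i <- 1L
    while (i <= n) {
      j <- min(i + config$batch_size - 1L, n)
      idx <- perm[i:j]
      batch <- train_samples[idx]
      if (!is.null(config$augmentation)) {
        for (k in seq_along(batch)) {
          ds <- derive_seed(config$seed, epoch * 1000003 + idx[k])
          batch[[k]] <- augment_pair(batch[[k]], config$augmentation, ds)
        }
      }
      b <- stack_samples(batch)
      fw <- model_forward(model, b$x, training = TRUE)
      # a zero learning rate is a strict no-op: neither the weights nor
      # the batch-norm running statistics move
      if (config$learning_rate > 0) model$buffers <- fw$buffers
      lf <- if (config$loss == "bce") bce_loss else dice_loss
      loss_sum <- loss_sum + lf(fw$p, b$y) * length(fw$p)
      acc_sum <- acc_sum + sum((fw$p >= 0.5) * 1 == b$y)
      npix <- npix + length(fw$p)
      if (config$learning_rate > 0) {
        dz <- loss_grad_logits(config$loss, fw$p, b$y)
        grads <- model_backward(model, fw$cache, dz)
        model$weights <- adam_step(model$weights, grads, state,
                                   config$learning_rate, config$beta1,
                                   config$beta2)
      }
      i <- j + 1L
    }
    val <- validate_model(model, val_samples, config$batch_size, config$loss)
    history[[epoch]] <- data.frame(epoch = epoch,
                                   train_loss = loss_sum / npix,
                                   train_acc = acc_sum / npix,
                                   val_loss = val$loss,
                                   val_acc = val$accuracy,
                                   val_dice = val$dice)
    if (verbose)
      message(sprintf(
        "epoch %3d  train loss %.4f acc %.4f | val loss %.4f acc %.4f dice %.4f",
        epoch, loss_sum / npix, acc_sum / npix, val$loss, val$accuracy,
        val$dice))
    if (val$loss < best$loss) {
      best <- list(loss = val$loss, weights = model$weights,
                   buffers = model$buffers, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
  }
  model$weights <- best$weights
  model$buffers <- best$buffers
  list(model = model,
       history = do.call(rbind, history[!vapply(history, is.null, logical(1))]),
       best_epoch = best$epoch)
}

#' Save a model checkpoint
#'
#' The checkpoint embeds the model configuration, all weights and the
#' batch-norm running statistics in one file.
#'
#' @param model A `segnet_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
checkpoint_save <- function(model, path) {
  stopifnot(inherits(model, "segnet_model"))
  saveRDS(list(format = "lesionseg-checkpoint-1",
               config = unclass(model$config),
               weights = model$weights,
               buffers = model$buffers), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file written by [checkpoint_save()].
#' @param config Optional [model_config()]; if supplied it must match
#'   the embedded configuration exactly, otherwise an error is raised.
#' @return The restored `segnet_model`; its forward outputs are
#'   bit-identical to the saved model's.
#' @export
checkpoint_load <- function(path, config = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  if (!identical(ck$format, "lesionseg-checkpoint-1"))
    stop("not a recognized checkpoint file: ", path)
  emb <- structure(ck$config, class = "segnet_config")
  if (!is.null(config)) {
    stopifnot(inherits(config, "segnet_config"))
    if (!identical(unclass(config), unclass(emb)))
      stop("checkpoint configuration does not match the requested config")
  }
  model <- with_seed(0L, build_model(emb))
  model$weights <- ck$weights
  model$buffers <- ck$buffers
  model
}
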