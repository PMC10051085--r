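# High-level modelling interface: one fitting function returning a
# classed object with the usual print / summary / predict / plot / coef
# methods, wrapping the lower-level build_model() + train_segnet()
# machinery.

#' Fit a lesion-segmentation network
#'
#' Builds the configured architecture, trains it on the supplied
#' samples with Adam, early stopping and (optionally) paired
#' augmentation, and returns a fitted-model object.
#'
#' @param train_samples,val_samples Non-empty lists of [image_sample()]
#'   objects, all at the same resolution.
#' @param architecture `"attresunet"` (default), `"attunet"` or
#'   `"unet"`.
#' @param depth,base_filters Architecture size; see [model_config()].
#' @param config Optional [train_config()]; built from `...` defaults
#'   otherwise.
#' @param verbose Print per-epoch progress.
#' @return An object of class `segnet`: list with `model`, `history`,
#'   `best_epoch`, `config` (training) and `call`.
#' @seealso [predict.segnet()], [plot.segnet()], [evaluate_dataset()]
#' @examples
#' \donttest{
#' scenes <- generate_dataset(scene_spec(size = c(32, 32)), 12, seed = 7)
#' parts <- split_dataset(scenes, dataset_split(0.6, 0.2, 0.2, seed = 7))
#' fit <- segnet(parts$train, parts$validation, depth = 2, base_filters = 4,
#'               config = train_config(batch_size = 4, epochs = 2,
#'                                     early_stop_patience = 2))
#' predict(fit, parts$test[[1]]$image, type = "mask")
#' }
#' @export
segnet <- function(train_samples, val_samples,
                   architecture = c("attresunet", "unet", "attunet"),
                   depth = 4L, base_filters = 64L,
                   config = train_config(), verbose = FALSE) {
  architecture <- match.arg(architecture)
  if (length(train_samples) == 0L) stop("no training samples")
  d <- dim(train_samples[[1L]]$image)
  mcfg <- model_config(architecture, input_size = d[1:2],
                       input_channels = d[3L], depth = depth,
                       base_filters = base_filters)
  set.seed(config$seed)
  model <- build_model(mcfg)
  out <- train_segnet(model, train_samples, val_samples, config, verbose)
  structure(list(model = out$model, history = out$history,
                 best_epoch = out$best_epoch, config = config,
                 call = match.call()),
            class = "segnet")
}

#' Predict from a fitted segmentation network
#'
#' @param object A [segnet()] fit.
#' @param newdata An H x W x C image, an H x W x C x N batch, or a list
#'   of [image_sample()] objects.
#' @param type `"prob"` for per-pixel probabilities, `"mask"` for
#'   thresholded binary masks.
#' @param threshold Binarization threshold for `type = "mask"`.
#' @param ... Unused.
#' @return H x W x N array of probabilities or binary values.
#' @export
predict.segnet <- function(object, newdata, type = c("prob", "mask"),
                           threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.array(newdata))
    newdata <- stack_samples(newdata)$x
  p <- forward_model(object$model, newdata)
  if (type == "prob") p else (p >= threshold) * 1
}

#' @export
print.segnet <- function(x, ...) {
  cat("Fitted segmentation network (", x$model$config$architecture, ")\n",
      sep = "")
  cat("  epochs run: ", nrow(x$history), " (best epoch ", x$best_epoch,
      ")\n", sep = "")
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final: train loss %.4f | val loss %.4f, val dice %.4f\n",
              last$train_loss, last$val_loss, last$val_dice))
  invisible(x)
}

#' @export
summary.segnet <- function(object, ...) {
  m <- object$model
  cat("Architecture:", m$config$architecture, "\n")
  print(m)
  cat("Blocks:\n")
  print(m$blocks, row.names = FALSE)
  best <- object$history[object$history$epoch == object$best_epoch, ]
  if (nrow(best))
    cat(sprintf("Best epoch %d: val loss %.4f, val dice %.4f\n",
                best$epoch, best$val_loss, best$val_dice))
  invisible(object)
}

#' Plot training and validation curves
#'
#' @param x A [segnet()] fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.segnet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Extract model parameters
#'
#' @param object A [segnet()] fit.
#' @param ... Unused.
#' @return The nested list of weight arrays.
#' @export
coef.segnet <- function(object, ...) object$model$weights
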