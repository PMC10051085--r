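# Pixelwise segmentation evaluation: confusion counts, Dice coefficient
# 2|A.B|/(|A|+|B|), Jaccard index |A.B|/|A u B|, and accuracy
# (TP+TN)/(TP+FP+FN+TN). When both masks are empty, Dice and Jaccard are
# defined as 1 (perfect agreement; avoids 0/0). No smoothing terms.

check_masks <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("mask dimensions differ: ", paste(dim(pred), collapse = "x"),
         " vs ", paste(dim(truth), collapse = "x"))
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("masks must be binary (values 0/1)")
}

#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth Binary matrices (or arrays) of equal dimensions;
#'   foreground is 1.
#' @return An object of class `confusion_counts`: a list with integer
#'   fields `tp`, `tn`, `fp`, `fn` summing to the pixel count.
#' @export
confusion_counts <- function(pred, truth) {
  check_masks(pred, truth)
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- length(pred) - tp - fp - fn
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' Dice coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#' @inheritParams confusion_counts
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth) {
  check_masks(pred, truth)
  inter <- sum(pred == 1 & truth == 1)
  size <- sum(pred == 1) + sum(truth == 1)
  if (size == 0) return(1)
  2 * inter / size
}

#' Jaccard index (intersection over union) of two binary masks
#'
#' `|A n B| / |A u B|`; 1 when both masks are empty.
#' @inheritParams confusion_counts
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(pred, truth) {
  check_masks(pred, truth)
  inter <- sum(pred == 1 & truth == 1)
  union <- sum(pred == 1 | truth == 1)
  if (union == 0) return(1)
  inter / union
}

#' Pixel accuracy from confusion counts
#'
#' `(TP + TN) / (TP + FP + FN + TN)`.
#' @param counts A [confusion_counts()] object.
#' @return A number in `[0, 1]`.
#' @export
pixel_accuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) stop("confusion counts are empty")
  (counts$tp + counts$tn) / total
}

#' Evaluate a model over a set of samples
#'
#' Predicts a binary mask for every sample and reports both per-image
#' mean metrics (the headline numbers) and metrics pooled over all
#' pixels, together with the pooled confusion counts.
#'
#' @param model A `segnet_model`.
#' @param samples List of [image_sample()] objects at the model's input
#'   size.
#' @param threshold Binarization threshold, see [predict_mask()].
#' @return An object of class `metrics_report`: list with `accuracy`,
#'   `dice`, `jaccard` (per-image means), `pooled` (same three computed
#'   from pooled counts), `counts` (pooled [confusion_counts()]),
#'   `n_images`, and `per_image` (data frame of per-image metrics).
#' @export
evaluate_dataset <- function(model, samples, threshold = 0.5) {
  if (length(samples) == 0L) stop("no samples to evaluate")
  per <- vector("list", length(samples))
  pooled <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    pred <- predict_mask(model, s$image, threshold)
    cc <- confusion_counts(pred, s$mask)
    pooled <- pooled + c(cc$tp, cc$tn, cc$fp, cc$fn)
    per[[i]] <- data.frame(id = s$id,
                           accuracy = pixel_accuracy(cc),
                           dice = dice_coefficient(pred, s$mask),
                           jaccard = jaccard_index(pred, s$mask))
  }
  per <- do.call(rbind, per)
  pooled_counts <- structure(as.list(pooled), class = "confusion_counts")
  pooled_dice <- if (2 * pooled[["tp"]] + pooled[["fp"]] + pooled[["fn"]] == 0) 1
                 else 2 * pooled[["tp"]] / (2 * pooled[["tp"]] + pooled[["fp"]] + pooled[["fn"]])
  pooled_jac <- if (pooled[["tp"]] + pooled[["fp"]] + pooled[["fn"]] == 0) 1
                else pooled[["tp"]] / (pooled[["tp"]] + pooled[["fp"]] + pooled[["fn"]])
  structure(list(accuracy = mean(per$accuracy),
                 dice = mean(per$dice),
                 jaccard = mean(per$jaccard),
                 pooled = list(accuracy = pixel_accuracy(pooled_counts),
                               dice = pooled_dice, jaccard = pooled_jac),
                 counts = pooled_counts,
                 n_images = nrow(per),
                 per_image = per),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n =", x$n_images, "images\n")
  cat(sprintf("  per-image mean: accuracy %.4f  dice %.4f  jaccard %.4f\n",
              x$accuracy, x$dice, x$jaccard))
  cat(sprintf("  pooled pixels:  accuracy %.4f  dice %.4f  jaccard %.4f\n",
              x$pooled$accuracy, x$pooled$dice, x$pooled$jaccard))
  invisible(x)
}

#' Write a metrics report as JSON and CSV
#'
#' @param report A [evaluate_dataset()] report.
#' @param json_path,csv_path Output paths; either may be `NULL` to skip.
#' @return The report, invisibly.
#' @export
write_metrics_report <- function(report, json_path = NULL, csv_path = NULL) {
  row <- data.frame(accuracy = report$accuracy, dice = report$dice,
                    jaccard = report$jaccard,
                    tp = report$counts$tp, tn = report$counts$tn,
                    fp = report$counts$fp, fn = report$counts$fn,
                    n_images = report$n_images)
  if (!is.null(json_path))
    jsonlite::write_json(c(as.list(row), list(pooled = report$pooled)),
                         json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(row, csv_path, row.names = FALSE)
  invisible(report)
}
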