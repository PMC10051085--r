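# YAML run configuration: one file describing the model, the training
# protocol, the augmentation policy and the data locations, consumed by
# the command-line interface and by scripts.

default_run_config <- function() {
  list(
    model = list(architecture = "attresunet", input_size = c(128L, 128L),
                 input_channels = 3L, depth = 4L, base_filters = 64L),
    train = list(batch_size = 40L, epochs = 50L, learning_rate = 1e-3,
                 beta1 = 0.9, beta2 = 0.99, early_stop_patience = 10L,
                 loss = "bce", seed = 1L),
    augmentation = list(enabled = TRUE, horizontal_flip = TRUE,
                        vertical_flip = TRUE, rotation_max_degrees = 20,
                        zoom_range = 0.1),
    data = list(dir = ".", train_fraction = 0.6, validation_fraction = 0.2,
                test_fraction = 0.2, split_seed = 1L),
    synth = list(n_samples = 200L, size = c(64L, 64L), n_lesions = 2L,
                 radius_range = c(4, 14), boundary_irregularity = 0.3,
                 noise_sigma = 0.03, seed = 1L)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read a YAML run configuration
#'
#' Unspecified fields fall back to the package defaults (128x128
#' attention residual U-Net, batch 40, up to 50 epochs, Adam 1e-3 with
#' beta1 0.9 / beta2 0.99, early-stop patience 10, flips/rotation/zoom
#' augmentation, 60/20/20 split).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Nested configuration list with sections `model`, `train`,
#'   `augmentation`, `data`, `synth`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

run_config_objects <- function(cfg) {
  pol <- NULL
  if (isTRUE(cfg$augmentation$enabled))
    pol <- augmentation_policy(cfg$augmentation$horizontal_flip,
                               cfg$augmentation$vertical_flip,
                               cfg$augmentation$rotation_max_degrees,
                               cfg$augmentation$zoom_range,
                               seed = cfg$train$seed)
  list(
    model = model_config(cfg$model$architecture,
                         input_size = cfg$model$input_size,
                         input_channels = cfg$model$input_channels,
                         depth = cfg$model$depth,
                         base_filters = cfg$model$base_filters),
    train = train_config(batch_size = cfg$train$batch_size,
                         epochs = cfg$train$epochs,
                         learning_rate = cfg$train$learning_rate,
                         beta1 = cfg$train$beta1, beta2 = cfg$train$beta2,
                         early_stop_patience = cfg$train$early_stop_patience,
                         loss = cfg$train$loss, seed = cfg$train$seed,
                         augmentation = pol),
    split = dataset_split(cfg$data$train_fraction,
                          cfg$data$validation_fraction,
                          cfg$data$test_fraction,
                          seed = cfg$data$split_seed))
}

write_manifest <- function(path, command, cfg, inputs, outputs) {
  man <- list(command = command,
              package = "lesionseg",
              version = as.character(utils::packageVersion("lesionseg")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = cfg, inputs = inputs, outputs = outputs)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
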