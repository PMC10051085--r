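# Assembly of the three architectures: U-Net, attention U-Net
# (attention-gated skips) and attention residual U-Net (residual encoder
# blocks plus attention-gated skips). One builder covers all three; the
# decoder is shared (upsample + convolution, plain convolution blocks,
# no residual structure) and differs only in how the skip connection is
# merged: plain concatenation, or attention gating then concatenation.

ARCHITECTURES <- c("unet", "attunet", "attresunet")

#' Segmentation model configuration
#'
#' @param architecture One of `"unet"`, `"attunet"`, `"attresunet"`.
#' @param input_size Integer vector `(H, W)`; both must be divisible by
#'   `2^depth`. Default 128 x 128, the working resolution of the method.
#' @param input_channels Image channels (3 for RGB).
#' @param depth Number of 2x downsampling stages.
#' @param base_filters Channel width of the first encoder stage; width
#'   doubles at each stage down to the bottleneck.
#' @return An object of class `segnet_config`.
#' @export
model_config <- function(architecture = c("attresunet", "unet", "attunet"),
                         input_size = c(128L, 128L),
                         input_channels = 3L,
                         depth = 4L,
                         base_filters = 64L) {
  architecture <- match.arg(architecture, ARCHITECTURES)
  input_size <- as.integer(input_size)
  depth <- as.integer(depth)
  base_filters <- as.integer(base_filters)
  if (length(input_size) != 2L || any(input_size < 1L))
    stop("input_size must be two positive integers")
  if (depth < 1L) stop("depth must be >= 1")
  if (base_filters < 1L) stop("base_filters must be >= 1")
  if (any(input_size %% 2L^depth != 0L))
    stop("input_size must be divisible by 2^depth = ", 2L^depth)
  structure(list(architecture = architecture,
                 input_size = input_size,
                 input_channels = as.integer(input_channels),
                 depth = depth,
                 base_filters = base_filters,
                 output_channels = 1L),
            class = "segnet_config")
}

#' Build a segmentation model
#'
#' Instantiates all block parameters for the configured architecture.
#' Weight initialization draws from the current RNG state; call
#' `set.seed()` beforehand for reproducible builds.
#'
#' Encoder stages use residual units for `attresunet` and plain
#' convolution blocks otherwise, each followed by 2x2 max pooling; the
#' channel width doubles per stage. The bottleneck follows the encoder
#' convention. Decoder stages upsample 2x (nearest neighbour followed by
#' a 3x3 convolution), merge the skip connection (gated for the
#' attention variants) by concatenation, and apply a plain convolution
#' block. A final 1x1 convolution and sigmoid produce the probability
#' map.
#'
#' @param config A [model_config()] object.
#' @return An object of class `segnet_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "segnet_config"))
  d <- config$depth
  bf <- config$base_filters
  attention <- config$architecture %in% c("attunet", "attresunet")
  residual <- config$architecture == "attresunet"
  enc_block_init <- if (residual) residual_block_init else conv_block_init

  widths <- bf * 2L^(0:(d - 1L))              # encoder stage widths
  wt <- list(enc = vector("list", d), up = vector("list", d),
             dec = vector("list", d))
  bf_ <- wt                                    # buffers mirror weights
  blocks <- list()

  cin <- config$input_channels
  for (i in seq_len(d)) {
    p <- enc_block_init(cin, widths[i])
    wt$enc[[i]] <- p$weights
    bf_$enc[[i]] <- p$buffers
    blocks[[length(blocks) + 1L]] <-
      data.frame(name = paste0("enc", i),
                 type = if (residual) "residual" else "conv",
                 in_channels = cin, out_channels = widths[i])
    cin <- widths[i]
  }
  bott_width <- bf * 2L^d
  p <- enc_block_init(cin, bott_width)
  wt$bottleneck <- p$weights
  bf_$bottleneck <- p$buffers
  blocks[[length(blocks) + 1L]] <-
    data.frame(name = "bottleneck",
               type = if (residual) "residual" else "conv",
               in_channels = cin, out_channels = bott_width)

  if (attention) {
    wt$att <- vector("list", d)
    bf_$att <- vector("list", d)
  }
  for (i in rev(seq_len(d))) {
    deep <- if (i == d) bott_width else widths[i + 1L]
    skip <- widths[i]
    up <- stage_init(3L, 3L, deep, skip)
    wt$up[[i]] <- up$weights
    bf_$up[[i]] <- up$buffers
    if (attention) {
      g <- attention_gate_init(skip, deep)
      wt$att[[i]] <- g$weights
      bf_$att[[i]] <- g$buffers
      blocks[[length(blocks) + 1L]] <-
        data.frame(name = paste0("att", i), type = "attention_gate",
                   in_channels = skip, out_channels = skip)
    }
    p <- conv_block_init(2L * skip, skip)
    wt$dec[[i]] <- p$weights
    bf_$dec[[i]] <- p$buffers
    blocks[[length(blocks) + 1L]] <-
      data.frame(name = paste0("dec", i), type = "conv",
                 in_channels = 2L * skip, out_channels = skip)
  }
  wt$head <- init_conv(1L, 1L, bf, config$output_channels)

  structure(list(config = config, weights = wt, buffers = bf_,
                 blocks = do.call(rbind, blocks)),
            class = "segnet_model")
}

# Full forward pass. x: (H, W, C, N). Returns probability map p, the
# pre-sigmoid logits, per-layer caches for backprop, and updated batch
# norm buffers.
model_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  wt <- model$weights
  bufs <- model$buffers
  d <- cfg$depth
  attention <- cfg$architecture %in% c("attunet", "attresunet")
  residual <- cfg$architecture == "attresunet"
  block_fwd <- if (residual) residual_block_fwd else conv_block_fwd

  cache <- list(enc = vector("list", d), pool = vector("list", d),
                up = vector("list", d), dec = vector("list", d),
                split = vector("list", d),
                att = if (attention) vector("list", d))
  skips <- vector("list", d)
  h <- x
  for (i in seq_len(d)) {
    b <- block_fwd(h, wt$enc[[i]], bufs$enc[[i]], training)
    bufs$enc[[i]] <- b$buffers
    cache$enc[[i]] <- b$cache
    skips[[i]] <- b$y
    mp <- nn_maxpool_fwd(b$y)
    cache$pool[[i]] <- list(argmax = mp$argmax, h = dim(b$y)[1L], w = dim(b$y)[2L])
    h <- mp$y
  }
  b <- block_fwd(h, wt$bottleneck, bufs$bottleneck, training)
  bufs$bottleneck <- b$buffers
  cache$bottleneck <- b$cache
  h <- b$y

  for (i in rev(seq_len(d))) {
    if (attention) {
      ag <- attention_gate_fwd(skips[[i]], h, wt$att[[i]], bufs$att[[i]], training)
      bufs$att[[i]] <- ag$buffers
      cache$att[[i]] <- ag$cache
      skip <- ag$gated
    } else {
      skip <- skips[[i]]
    }
    upx <- nn_upsample_fwd(h)
    us <- stage_fwd(upx, wt$up[[i]], bufs$up[[i]], training)
    bufs$up[[i]] <- us$buffers
    cache$up[[i]] <- us$cache
    merged <- nn_concat(skip, us$y)
    cache$split[[i]] <- dim(skip)[3L]
    db <- conv_block_fwd(merged, wt$dec[[i]], bufs$dec[[i]], training)
    bufs$dec[[i]] <- db$buffers
    cache$dec[[i]] <- db$cache
    h <- db$y
  }
  z <- nn_conv_fwd(h, wt$head$w, wt$head$b, 1L, 0L)
  p <- nn_sigmoid(z)
  cache$head_x <- h
  list(p = p, z = z, cache = cache, buffers = bufs)
}

# Backward pass from the gradient with respect to the pre-sigmoid
# logits. Returns the gradient tree matching model$weights.
model_backward <- function(model, cache, dz) {
  cfg <- model$config
  wt <- model$weights
  d <- cfg$depth
  attention <- cfg$architecture %in% c("attunet", "attresunet")
  residual <- cfg$architecture == "attresunet"
  block_bwd <- if (residual) residual_block_bwd else conv_block_bwd

  gr <- list(enc = vector("list", d), up = vector("list", d),
             dec = vector("list", d),
             att = if (attention) vector("list", d))

  hb <- nn_conv_bwd(cache$head_x, wt$head$w, dz, 1L, 0L)
  gr$head <- list(w = hb$dw, b = hb$db)
  dh <- hb$dx

  dskips <- vector("list", d)
  for (i in seq_len(d)) {       # decoder ran depth..1; reverse order is 1..depth
    db <- conv_block_bwd(cache$dec[[i]], dh, wt$dec[[i]])
    gr$dec[[i]] <- db$grads
    csplit <- cache$split[[i]]
    dmerged <- db$dx
    dskip <- dmerged[, , seq_len(csplit), , drop = FALSE]
    dup <- dmerged[, , csplit + seq_len(dim(dmerged)[3L] - csplit), , drop = FALSE]
    us <- stage_bwd(cache$up[[i]], dup, wt$up[[i]])
    gr$up[[i]] <- us$grads
    dh_deep <- nn_upsample_bwd(us$dx)
    if (attention) {
      ab <- attention_gate_bwd(cache$att[[i]], dskip, NULL, wt$att[[i]])
      gr$att[[i]] <- ab$grads
      dskips[[i]] <- ab$dxl
      dh_deep <- dh_deep + ab$dg
    } else {
      dskips[[i]] <- dskip
    }
    dh <- dh_deep
  }

  bb <- block_bwd(cache$bottleneck, dh, wt$bottleneck)
  gr$bottleneck <- bb$grads
  dh <- bb$dx
  for (i in rev(seq_len(d))) {
    dpre <- nn_maxpool_bwd(dh, cache$pool[[i]]$argmax,
                           cache$pool[[i]]$h, cache$pool[[i]]$w)
    dpre <- dpre + dskips[[i]]
    eb <- block_bwd(cache$enc[[i]], dpre, wt$enc[[i]])
    gr$enc[[i]] <- eb$grads
    dh <- eb$dx
  }
  gr
}

#' Run a model on a batch of images
#'
#' Inference-mode forward pass: batch normalization uses the stored
#' running statistics, so the output is deterministic.
#'
#' @param model A `segnet_model`.
#' @param images Either a single H x W x C image or an H x W x C x N
#'   batch, values in `[0, 1]`.
#' @return An H x W x N array of per-pixel foreground probabilities in
#'   `(0, 1)`.
#' @export
forward_model <- function(model, images) {
  x <- as_batch(images, model$config)
  p <- model_forward(model, x, training = FALSE)$p
  array(p, dim(p)[c(1L, 2L, 4L)])
}

as_batch <- function(images, config) {
  d <- dim(images)
  if (length(d) == 3L) dim(images) <- c(d, 1L)
  d <- dim(images)
  if (d[1L] != config$input_size[1L] || d[2L] != config$input_size[2L])
    stop("image size ", d[1L], "x", d[2L], " does not match model input ",
         config$input_size[1L], "x", config$input_size[2L])
  if (d[3L] != config$input_channels)
    stop("expected ", config$input_channels, " channels, got ", d[3L])
  images
}

#' Predict a binary mask for one image
#'
#' @param model A `segnet_model`.
#' @param image An H x W x C image in `[0, 1]` at the model input size.
#' @param threshold Probability cut in `(0, 1)`; pixels with probability
#'   `>= threshold` become foreground. Default 0.5.
#' @return An H x W binary matrix.
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  p <- forward_model(model, image)
  (p[, , 1L] >= threshold) * 1
}

#' Number of trainable parameters
#' @param model A `segnet_model`.
#' @return Integer count of all weights and biases.
#' @export
n_parameters <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(model$weights)
  n
}

#' Count blocks of a given type in a model
#' @param model A `segnet_model`.
#' @param type One of `"residual"`, `"conv"`, `"attention_gate"`.
#' @return Integer count (encoder + bottleneck + decoder as applicable).
#' @export
n_blocks <- function(model, type) {
  sum(model$blocks$type == type)
}

#' @export
print.segnet_model <- function(x, ...) {
  cfg <- x$config
  cat("<segnet_model> ", cfg$architecture, "\n", sep = "")
  cat("  input: ", cfg$input_size[1L], "x", cfg$input_size[2L], "x",
      cfg$input_channels, ", depth ", cfg$depth, ", base filters ",
      cfg$base_filters, "\n", sep = "")
  cat("  parameters: ", n_parameters(x), "\n", sep = "")
  invisible(x)
}
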