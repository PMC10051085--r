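# Building blocks of the segmentation networks.
#
# Internally every feature map is an (H, W, C, N) array and every block
# carries a `weights` list (trainable) plus a `buffers` list (batch-norm
# running statistics). The exported block functions present the
# single-map C x H x W view that is natural when reasoning about one
# image, and delegate to the batched internals.

init_conv <- function(kh, kw, cin, cout, seed_scale = 1) {
  # He initialization: variance 2 / fan-in, the standard choice for
  # ReLU-activated convolution stacks.
  sd <- sqrt(2 / (kh * kw * cin)) * seed_scale
  list(w = array(stats::rnorm(kh * kw * cin * cout, sd = sd),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
}

init_bn <- function(c) {
  list(weights = list(gamma = rep(1, c), beta = numeric(c)),
       buffers = list(rmean = numeric(c), rvar = rep(1, c)))
}

# one conv -> batch norm -> ReLU stage
stage_init <- function(kh, kw, cin, cout) {
  bn <- init_bn(cout)
  list(weights = c(init_conv(kh, kw, cin, cout), bn$weights),
       buffers = bn$buffers)
}

stage_fwd <- function(x, wt, bf, training, stride = 1L, pad = 1L) {
  z <- nn_conv_fwd(x, wt$w, wt$b, stride, pad)
  bn <- nn_bn_fwd(z, wt$gamma, wt$beta, bf$rmean, bf$rvar, training)
  y <- nn_relu_fwd(bn$y)
  list(y = y,
       cache = list(x = x, bncache = bn$cache, pre_relu = bn$y,
                    stride = stride, pad = pad, training = training),
       buffers = list(rmean = bn$rmean, rvar = bn$rvar))
}

stage_bwd <- function(cache, dy, wt) {
  dpre <- nn_relu_bwd(cache$pre_relu, dy)
  bnb <- if (cache$training) nn_bn_bwd(cache$bncache, dpre, wt$gamma)
         else nn_bn_bwd_inference(cache$bncache, dpre, wt$gamma)
  cb <- nn_conv_bwd(cache$x, wt$w, bnb$dx, cache$stride, cache$pad)
  list(dx = cb$dx,
       grads = list(w = cb$dw, b = cb$db, gamma = bnb$dgamma, beta = bnb$dbeta))
}

## ---- plain convolution block: two 3x3 conv/BN/ReLU stages ----

conv_block_init <- function(cin, cout) {
  s1 <- stage_init(3L, 3L, cin, cout)
  s2 <- stage_init(3L, 3L, cout, cout)
  list(weights = list(s1 = s1$weights, s2 = s2$weights),
       buffers = list(s1 = s1$buffers, s2 = s2$buffers),
       cin = cin, cout = cout)
}

conv_block_fwd <- function(x, wt, bf, training) {
  a <- stage_fwd(x, wt$s1, bf$s1, training)
  b <- stage_fwd(a$y, wt$s2, bf$s2, training)
  list(y = b$y, cache = list(s1 = a$cache, s2 = b$cache),
       buffers = list(s1 = a$buffers, s2 = b$buffers))
}

conv_block_bwd <- function(cache, dy, wt) {
  b <- stage_bwd(cache$s2, dy, wt$s2)
  a <- stage_bwd(cache$s1, b$dx, wt$s1)
  list(dx = a$dx, grads = list(s1 = a$grads, s2 = b$grads))
}

## ---- residual unit: y = F(x) + shortcut(x) ----
# F is the two-stage convolution block; the shortcut is the identity when
# channel counts agree and a 1x1 convolution projection otherwise.

residual_block_init <- function(cin, cout) {
  p <- conv_block_init(cin, cout)
  if (cin != cout) p$weights$sc <- init_conv(1L, 1L, cin, cout)
  p
}

residual_block_fwd <- function(x, wt, bf, training) {
  f <- conv_block_fwd(x, wt, bf, training)
  if (is.null(wt$sc)) {
    y <- f$y + x
  } else {
    y <- f$y + nn_conv_fwd(x, wt$sc$w, wt$sc$b, 1L, 0L)
  }
  list(y = y, cache = c(f$cache, list(x = x)), buffers = f$buffers)
}

residual_block_bwd <- function(cache, dy, wt) {
  f <- conv_block_bwd(cache, dy, wt)
  if (is.null(wt$sc)) {
    f$dx <- f$dx + dy
  } else {
    sb <- nn_conv_bwd(cache$x, wt$sc$w, dy, 1L, 0L)
    f$dx <- f$dx + sb$dx
    f$grads$sc <- list(w = sb$dw, b = sb$db)
  }
  f
}

## ---- additive attention gate ----
# x_l (encoder features, C_x at full stage resolution) is brought down to
# the gating signal's resolution by a strided 1x1 convolution; g (decoder
# features one level deeper, C_g channels) passes a 1x1 convolution; both
# land in an intermediate space of `cint` channels. Their ReLU'd sum goes
# through a 1x1 convolution to one channel and a sigmoid, giving the
# attention coefficients at the coarse resolution, which are upsampled
# bilinearly and multiplied into x_l. Each gate convolution is followed
# by batch normalization before the nonlinearity.

attention_gate_init <- function(cx, cg, cint = NULL) {
  if (is.null(cint)) cint <- max(1L, cg %/% 2L)
  th <- stage_init(1L, 1L, cx, cint)   # reuses conv+BN containers
  ph <- stage_init(1L, 1L, cg, cint)
  ps <- stage_init(1L, 1L, cint, 1L)
  list(weights = list(theta = th$weights, phi = ph$weights, psi = ps$weights),
       buffers = list(theta = th$buffers, phi = ph$buffers, psi = ps$buffers),
       cx = cx, cg = cg, cint = cint)
}

attention_gate_fwd <- function(xl, g, wt, bf, training) {
  dx <- dim(xl); dg <- dim(g)
  if (dx[1L] %% dg[1L] != 0L || dx[2L] %% dg[2L] != 0L)
    stop("spatial dims of x_l must be integer multiples of g's")
  stride <- dx[1L] %/% dg[1L]
  if (dx[2L] %/% dg[2L] != stride)
    stop("x_l / g spatial ratio must match in both axes")

  tz <- nn_conv_fwd(xl, wt$theta$w, wt$theta$b, stride, 0L)
  tb <- nn_bn_fwd(tz, wt$theta$gamma, wt$theta$beta,
                  bf$theta$rmean, bf$theta$rvar, training)
  pz <- nn_conv_fwd(g, wt$phi$w, wt$phi$b, 1L, 0L)
  pb <- nn_bn_fwd(pz, wt$phi$gamma, wt$phi$beta,
                  bf$phi$rmean, bf$phi$rvar, training)
  s <- tb$y + pb$y
  f <- nn_relu_fwd(s)
  qz <- nn_conv_fwd(f, wt$psi$w, wt$psi$b, 1L, 0L)
  qb <- nn_bn_fwd(qz, wt$psi$gamma, wt$psi$beta,
                  bf$psi$rmean, bf$psi$rvar, training)
  alpha_lo <- nn_sigmoid(qb$y)                      # (h/s, w/s, 1, n)
  Ah <- interp_matrix(dg[1L], dx[1L])
  Aw <- interp_matrix(dg[2L], dx[2L])
  alpha <- if (stride == 1L) alpha_lo else nn_resize_lin(alpha_lo, Ah, Aw)
  gated <- sweep_alpha(xl, alpha)
  list(gated = gated, alpha = alpha,
       cache = list(xl = xl, g = g, stride = stride, training = training,
                    tcache = tb$cache, pcache = pb$cache, qcache = qb$cache,
                    pre_relu = s, f = f, alpha_lo = alpha_lo, alpha = alpha,
                    Ah = Ah, Aw = Aw),
       buffers = list(theta = list(rmean = tb$rmean, rvar = tb$rvar),
                      phi = list(rmean = pb$rmean, rvar = pb$rvar),
                      psi = list(rmean = qb$rmean, rvar = qb$rvar)))
}

# multiply a one-channel map into every channel of x
sweep_alpha <- function(x, alpha) {
  d <- dim(x)
  a <- array(alpha[, , 1L, ], c(d[1L], d[2L], d[4L]))
  x * as.vector(aperm(array(rep(a, d[3L]), c(d[1L], d[2L], d[4L], d[3L])),
                      c(1L, 2L, 4L, 3L)))
}

attention_gate_bwd <- function(cache, dgated, dalpha_extra, wt) {
  d <- dim(cache$xl)
  # d(gated)/d(alpha): sum over channels of dgated * xl
  prod <- dgated * cache$xl
  dalpha <- array(0, dim(cache$alpha))
  dalpha[, , 1L, ] <- colSums(aperm(prod, c(3L, 1L, 2L, 4L)))  # sum channels
  if (!is.null(dalpha_extra)) dalpha <- dalpha + dalpha_extra
  dxl_direct <- sweep_alpha(dgated, cache$alpha)

  dalpha_lo <- if (cache$stride == 1L) dalpha
               else nn_resize_lin_bwd(dalpha, cache$Ah, cache$Aw)
  dqb <- dalpha_lo * cache$alpha_lo * (1 - cache$alpha_lo)
  bnb <- if (cache$training) nn_bn_bwd(cache$qcache, dqb, wt$psi$gamma)
         else nn_bn_bwd_inference(cache$qcache, dqb, wt$psi$gamma)
  qcb <- nn_conv_bwd(cache$f, wt$psi$w, bnb$dx, 1L, 0L)
  ds <- nn_relu_bwd(cache$pre_relu, qcb$dx)

  tbn <- if (cache$training) nn_bn_bwd(cache$tcache, ds, wt$theta$gamma)
         else nn_bn_bwd_inference(cache$tcache, ds, wt$theta$gamma)
  tcb <- nn_conv_bwd(cache$xl, wt$theta$w, tbn$dx, cache$stride, 0L)
  pbn <- if (cache$training) nn_bn_bwd(cache$pcache, ds, wt$phi$gamma)
         else nn_bn_bwd_inference(cache$pcache, ds, wt$phi$gamma)
  pcb <- nn_conv_bwd(cache$g, wt$phi$w, pbn$dx, 1L, 0L)

  list(dxl = dxl_direct + tcb$dx,
       dg = pcb$dx,
       grads = list(
         theta = list(w = tcb$dw, b = tcb$db, gamma = tbn$dgamma, beta = tbn$dbeta),
         phi = list(w = pcb$dw, b = pcb$db, gamma = pbn$dgamma, beta = pbn$dbeta),
         psi = list(w = qcb$dw, b = qcb$db, gamma = bnb$dgamma, beta = bnb$dbeta)))
}

## ---- exported single-map views ----

chw_to_batch <- function(x) {
  d <- dim(x)
  if (length(d) != 3L) stop("a feature map must be a C x H x W array")
  array(aperm(x, c(2L, 3L, 1L)), c(d[2L], d[3L], d[1L], 1L))
}

batch_to_chw <- function(x) {
  d <- dim(x)
  aperm(array(x, d[1:3]), c(3L, 1L, 2L))
}

#' Parameters for a plain convolution block
#'
#' Two successive stages of 3x3 same-padding convolution, batch
#' normalization and ReLU. Weights use He initialization from the current
#' RNG state; batch-norm scale/shift start at identity and the running
#' statistics at mean 0, variance 1.
#'
#' @param in_channels,out_channels Channel counts of input and output.
#' @return A parameter object accepted by [conv_block()].
#' @export
conv_block_params <- function(in_channels, out_channels) {
  p <- conv_block_init(as.integer(in_channels), as.integer(out_channels))
  structure(p, class = "conv_block_params")
}

#' Apply a plain convolution block to a feature map
#'
#' @param x A C x H x W array (channels first).
#' @param params Object from [conv_block_params()].
#' @param training Use batch statistics (`TRUE`) or the frozen running
#'   statistics (`FALSE`) in batch normalization.
#' @return A C' x H x W array; all entries are nonnegative (ReLU output).
#' @export
conv_block <- function(x, params, training = FALSE) {
  xb <- chw_to_batch(x)
  if (dim(xb)[3L] != params$cin)
    stop("input has ", dim(xb)[3L], " channels, block expects ", params$cin)
  batch_to_chw(conv_block_fwd(xb, params$weights, params$buffers, training)$y)
}

#' Parameters for a residual unit
#'
#' The unit computes `F(x) + shortcut(x)` where `F` is a two-stage
#' convolution block and the shortcut is the identity when input and
#' output channel counts agree, or a 1x1 convolution projection
#' otherwise.
#'
#' @inheritParams conv_block_params
#' @return A parameter object accepted by [residual_block()].
#' @export
residual_block_params <- function(in_channels, out_channels) {
  p <- residual_block_init(as.integer(in_channels), as.integer(out_channels))
  structure(p, class = "residual_block_params")
}

#' Apply a residual unit to a feature map
#'
#' @inheritParams conv_block
#' @param params Object from [residual_block_params()].
#' @return A C' x H x W array equal to `F(x) + shortcut(x)`.
#' @export
residual_block <- function(x, params, training = FALSE) {
  xb <- chw_to_batch(x)
  if (dim(xb)[3L] != params$cin)
    stop("input has ", dim(xb)[3L], " channels, block expects ", params$cin)
  batch_to_chw(residual_block_fwd(xb, params$weights, params$buffers, training)$y)
}

#' Parameters for an additive attention gate
#'
#' @param x_channels Channels of the encoder feature map `x_l`.
#' @param g_channels Channels of the gating signal `g` (one level deeper).
#' @param inter_channels Width of the shared intermediate space; defaults
#'   to half the gating channels (minimum 1).
#' @return A parameter object accepted by [attention_gate()].
#' @export
attention_gate_params <- function(x_channels, g_channels, inter_channels = NULL) {
  p <- attention_gate_init(as.integer(x_channels), as.integer(g_channels),
                           if (!is.null(inter_channels)) as.integer(inter_channels))
  structure(p, class = "attention_gate_params")
}

#' Apply an attention gate to a skip connection
#'
#' Computes per-location attention coefficients in `[0, 1]` from the
#' encoder features `x_l` and the deeper gating signal `g`, and rescales
#' `x_l` by them.
#'
#' @param x_l A C_x x H x W array of encoder features.
#' @param g A C_g x H_g x W_g array with `H_g <= H`; `H` must be an
#'   integer multiple of `H_g`.
#' @param params Object from [attention_gate_params()].
#' @param training Batch-norm mode as in [conv_block()].
#' @return A list with `gated` (C_x x H x W, equal to the coefficients
#'   broadcast over channels times `x_l`) and `coefficients`
#'   (1 x H x W, each value in `[0, 1]`).
#' @export
attention_gate <- function(x_l, g, params, training = FALSE) {
  xb <- chw_to_batch(x_l)
  gb <- chw_to_batch(g)
  out <- attention_gate_fwd(xb, gb, params$weights, params$buffers, training)
  list(gated = batch_to_chw(out$gated),
       coefficients = batch_to_chw(out$alpha))
}
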