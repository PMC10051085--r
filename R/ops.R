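# Internal tensor layers operating on (H, W, C, N) arrays.
#
# Convolution, pooling and nearest upsampling live in src/ops.cpp; the
# elementwise layers and batch normalization are vectorized R. Each layer
# has an explicit forward (returning what its backward needs) and backward
# (the exact adjoint). Gradients were validated against central finite
# differences; see tests.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

nn_conv_fwd <- function(x, w, b, stride = 1L, pad = 0L) {
  .conv2d_forward(x, w, b, as.integer(stride), as.integer(pad))
}

nn_conv_bwd <- function(x, w, dy, stride = 1L, pad = 0L) {
  .conv2d_backward(x, w, dy, as.integer(stride), as.integer(pad))
}

# (H,W,C,N) -> (H*W*N, C) with channel as the column
as_channel_matrix <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(m) <- c(d[1L] * d[2L] * d[4L], d[3L])
  m
}

from_channel_matrix <- function(m, d) {
  dim(m) <- c(d[1L], d[2L], d[4L], d[3L])
  aperm(m, c(1L, 2L, 4L, 3L))
}

# Batch normalization over (H, W, N) per channel. In training mode the
# batch statistics are used (biased variance, the convention of the
# original formulation) and the running statistics are updated in place
# semantics by returning them; in inference mode the running statistics
# are frozen.
nn_bn_fwd <- function(x, gamma, beta, rmean, rvar, training) {
  d <- dim(x)
  xm <- as_channel_matrix(x)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu, "-")
    v <- colMeans(xc * xc)
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(xc, 2L, invstd, "*")
    m <- nrow(xm)
    unbias <- if (m > 1L) m / (m - 1L) else 1
    rmean <- (1 - BN_MOMENTUM) * rmean + BN_MOMENTUM * mu
    rvar <- (1 - BN_MOMENTUM) * rvar + BN_MOMENTUM * v * unbias
  } else {
    invstd <- 1 / sqrt(rvar + BN_EPS)
    xhat <- sweep(sweep(xm, 2L, rmean, "-"), 2L, invstd, "*")
  }
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = from_channel_matrix(y, d),
       cache = list(xhat = xhat, invstd = invstd, d = d),
       rmean = rmean, rvar = rvar)
}

# Backward through training-mode batch normalization.
nn_bn_bwd <- function(cache, dy, gamma) {
  dym <- as_channel_matrix(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, gamma, "*")
  mu1 <- colMeans(dxhat)
  mu2 <- colMeans(dxhat * xhat)
  dxm <- dxhat - rep(mu1, each = nrow(dxhat)) - xhat * rep(mu2, each = nrow(dxhat))
  dxm <- sweep(dxm, 2L, cache$invstd, "*")
  list(dx = from_channel_matrix(dxm, cache$d), dgamma = dgamma, dbeta = dbeta)
}

# Backward through inference-mode batch normalization (an affine map).
nn_bn_bwd_inference <- function(cache, dy, gamma) {
  dym <- as_channel_matrix(dy)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxm <- sweep(dym, 2L, gamma * cache$invstd, "*")
  list(dx = from_channel_matrix(dxm, cache$d), dgamma = dgamma, dbeta = dbeta)
}

nn_relu_fwd <- function(x) x * (x > 0)

nn_relu_bwd <- function(x, dy) dy * (x > 0)

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

nn_maxpool_fwd <- function(x) .maxpool2_forward(x)

nn_maxpool_bwd <- function(dy, argmax, h, w) {
  .maxpool2_backward(dy, argmax, as.integer(h), as.integer(w))
}

nn_upsample_fwd <- function(x) .upsample2_forward(x)

nn_upsample_bwd <- function(dy) .upsample2_backward(dy)

nn_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

# Linear (align-corners) interpolation matrix mapping n_in samples onto
# n_out samples; each row holds the two blending weights.
interp_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  if (n_in == 1L) {
    A[, 1L] <- 1
    return(A)
  }
  src <- seq(1, n_in, length.out = n_out)
  lo <- pmin(floor(src), n_in - 1L)
  frac <- src - lo
  for (i in seq_len(n_out)) {
    A[i, lo[i]] <- A[i, lo[i]] + (1 - frac[i])
    A[i, lo[i] + 1L] <- A[i, lo[i] + 1L] + frac[i]
  }
  A
}

# Separable bilinear resize of (h, w, c, n) to (h2, w2, c, n) via the two
# interpolation matrices; used to upsample attention coefficients and to
# resize images. Returns the output; the backward is the transpose map.
nn_resize_lin <- function(x, Ah, Aw) {
  d <- dim(x)
  h2 <- nrow(Ah); w2 <- nrow(Aw)
  dim(x) <- c(d[1L], d[2L] * d[3L] * d[4L])
  t1 <- Ah %*% x                               # h2 x (w c n)
  dim(t1) <- c(h2, d[2L], d[3L] * d[4L])
  t1 <- aperm(t1, c(2L, 1L, 3L))               # w x h2 x (c n)
  dim(t1) <- c(d[2L], h2 * d[3L] * d[4L])
  t2 <- Aw %*% t1                              # w2 x (h2 c n)
  dim(t2) <- c(w2, h2, d[3L], d[4L])
  aperm(t2, c(2L, 1L, 3L, 4L))
}

nn_resize_lin_bwd <- function(dy, Ah, Aw) {
  nn_resize_lin(dy, t(Ah), t(Aw))
}

# Nearest-neighbour resize (value-set preserving; used for masks).
resize_nearest_2d <- function(m, h2, w2) {
  h <- nrow(m); w <- ncol(m)
  ri <- round(seq(1, h, length.out = h2))
  ci <- round(seq(1, w, length.out = w2))
  m[ri, ci, drop = FALSE]
}
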