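# Shared fixtures and independent oracles, all built in code.

# brute-force per-pixel confusion loop, the oracle the vectorized
# metrics are checked against
oracle_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; t <- truth[i, j]
      if (p == 1 && t == 1) tp <- tp + 1L
      else if (p == 1 && t == 0) fp <- fp + 1L
      else if (p == 0 && t == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

oracle_dice <- function(pred, truth) {
  cc <- oracle_confusion(pred, truth)
  if (2 * cc$tp + cc$fp + cc$fn == 0) return(1)
  2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
}

oracle_jaccard <- function(pred, truth) {
  cc <- oracle_confusion(pred, truth)
  if (cc$tp + cc$fp + cc$fn == 0) return(1)
  cc$tp / (cc$tp + cc$fp + cc$fn)
}

random_mask <- function(h, w, p = 0.5) {
  matrix(rbinom(h * w, 1, p), h, w)
}

# a small model for structural and IO tests (never trained)
tiny_model <- function(arch = "attresunet", size = c(16L, 16L), depth = 2L,
                       base_filters = 2L, seed = 1L) {
  withr_seed <- seed
  set.seed(withr_seed)
  build_model(model_config(arch, input_size = size, input_channels = 3L,
                           depth = depth, base_filters = base_filters))
}

random_samples <- function(n, h = 16L, w = 16L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    image_sample(array(runif(h * w * 3), c(h, w, 3L)),
                 random_mask(h, w, 0.3), sprintf("s%03d", i))
  })
}

# direct (non-im2col) convolution oracle for small inputs
oracle_conv <- function(x, w, b, stride = 1L, pad = 0L) {
  d <- dim(x); kd <- dim(w)
  hp <- d[1] + 2 * pad; wp <- d[2] + 2 * pad
  xp <- array(0, c(hp, wp, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  ho <- (hp - kd[1]) %/% stride + 1L
  wo <- (wp - kd[2]) %/% stride + 1L
  y <- array(0, c(ho, wo, kd[4], d[4]))
  for (n in seq_len(d[4])) for (o in seq_len(kd[4]))
    for (i in seq_len(ho)) for (j in seq_len(wo)) {
      acc <- b[o]
      for (c in seq_len(d[3])) for (ky in seq_len(kd[1])) for (kx in seq_len(kd[2]))
        acc <- acc + xp[(i - 1) * stride + ky, (j - 1) * stride + kx, c, n] *
          w[ky, kx, c, o]
      y[i, j, o, n] <- acc
    }
  y
}
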