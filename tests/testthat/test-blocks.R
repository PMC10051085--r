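# Network building blocks: shape contracts, the residual identity,
# attention-gate arithmetic, and hand-computed scalar oracles.

# identity-scale factor batch norm applies at default running stats
bn_id <- function(v) v / sqrt(1 + lesionseg:::BN_EPS)

test_that("conv_block preserves spatial dims, maps channels, outputs >= 0", {
  set.seed(30)
  for (shape in list(c(3, 16, 16), c(1, 8, 12), c(4, 6, 6))) {
    x <- array(rnorm(prod(shape)), shape)
    p <- conv_block_params(shape[1], 5)
    y <- conv_block(x, p)
    expect_equal(dim(y), c(5, shape[2], shape[3]))
    expect_true(all(y >= 0))
  }
  p <- conv_block_params(3, 4)
  expect_error(conv_block(array(0, c(2, 8, 8)), p), "channels")
})

test_that("conv_block maps zero input to zero output (zero bias, identity BN)", {
  set.seed(31)
  p <- conv_block_params(2, 3)
  y <- conv_block(array(0, c(2, 8, 8)), p)
  expect_equal(y, array(0, c(3, 8, 8)))
})

test_that("residual unit with zeroed transformation is the identity, bit-exact", {
  set.seed(32)
  for (trial in 1:50) {
    p <- residual_block_params(3, 3)
    p$weights$s2$w[] <- 0
    p$weights$s2$b[] <- 0
    x <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
    expect_identical(residual_block(x, p), x)
  }
})

test_that("residual unit projects the shortcut when channels change", {
  set.seed(33)
  x <- array(rnorm(16 * 8 * 8), c(16, 8, 8))
  p <- residual_block_params(16, 32)
  y <- residual_block(x, p)
  expect_equal(dim(y), c(32, 8, 8))
  expect_false(is.null(p$weights$sc))
  # equal channels: no projection allocated
  expect_null(residual_block_params(8, 8)$weights$sc)
})

test_that("residual unit on a 1x1 map matches scalar arithmetic", {
  p <- residual_block_params(1, 1)
  # hand-set every kernel: center taps only, known scalars
  p$weights$s1$w[] <- 0; p$weights$s1$w[2, 2, 1, 1] <- 2; p$weights$s1$b <- 0.5
  p$weights$s2$w[] <- 0; p$weights$s2$w[2, 2, 1, 1] <- -3; p$weights$s2$b <- 1
  x <- array(0.7, c(1, 1, 1))
  # stage 1: relu(bn(2 * 0.7 + 0.5)); stage 2: relu(bn(-3 * h1 + 1)); + x
  h1 <- max(0, bn_id(2 * 0.7 + 0.5))
  h2 <- max(0, bn_id(-3 * h1 + 1))
  expect_equal(residual_block(x, p)[1, 1, 1], h2 + 0.7, tolerance = 1e-12)
})

test_that("attention coefficients lie in [0,1] for 100 random input pairs", {
  set.seed(34)
  for (trial in 1:100) {
    cx <- sample(1:3, 1); cg <- sample(1:4, 1)
    p <- attention_gate_params(cx, cg)
    xl <- array(rnorm(cx * 8 * 8, sd = 2), c(cx, 8, 8))
    g <- array(rnorm(cg * 4 * 4, sd = 2), c(cg, 4, 4))
    out <- attention_gate(xl, g, p)
    expect_true(all(out$coefficients >= 0 & out$coefficients <= 1))
    expect_equal(dim(out$coefficients), c(1, 8, 8))
    expect_equal(dim(out$gated), c(cx, 8, 8))
  }
})

test_that("a zero-weight gate yields alpha = 0.5 and halves the input", {
  set.seed(35)
  p <- attention_gate_params(2, 4)
  for (nm in c("theta", "phi", "psi")) {
    p$weights[[nm]]$w[] <- 0
    p$weights[[nm]]$b[] <- 0
  }
  xl <- array(rnorm(2 * 8 * 8), c(2, 8, 8))
  g <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  out <- attention_gate(xl, g, p)
  expect_equal(out$coefficients, array(0.5, c(1, 8, 8)))
  expect_equal(out$gated, 0.5 * xl)
})

test_that("a gate saturated toward alpha = 1 passes x_l through unchanged", {
  set.seed(36)
  p <- attention_gate_params(2, 4)
  p$weights$psi$w[] <- 0
  p$weights$psi$b[] <- 50          # sigmoid(bn(50)) = 1 to double precision
  xl <- array(rnorm(2 * 8 * 8), c(2, 8, 8))
  g <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  out <- attention_gate(xl, g, p)
  expect_equal(out$gated, xl, tolerance = 1e-12)
})

test_that("a 1-channel 2x2 / 1x1 gate matches a hand-computed forward pass", {
  p <- attention_gate_params(1, 1, inter_channels = 1)
  p$weights$theta$w[] <- 1; p$weights$theta$b[] <- 0
  p$weights$phi$w[] <- 1; p$weights$phi$b[] <- 0
  p$weights$psi$w[] <- 1; p$weights$psi$b[] <- 0
  xl <- array(c(0.2, -0.4, 0.6, 0.8), c(1, 2, 2))   # (c, h, w)
  g <- array(0.3, c(1, 1, 1))
  out <- attention_gate(xl, g, p)
  # strided 1x1 conv on x_l picks the top-left element (stride 2)
  theta <- bn_id(xl[1, 1, 1])
  phi <- bn_id(g[1, 1, 1])
  f <- max(0, theta + phi)
  a <- 1 / (1 + exp(-bn_id(f)))
  # one coarse coefficient upsampled bilinearly is constant
  expect_equal(out$coefficients, array(a, c(1, 2, 2)), tolerance = 1e-12)
  expect_equal(out$gated, a * xl, tolerance = 1e-12)
})

test_that("gate rejects non-integer spatial ratios", {
  p <- attention_gate_params(1, 1)
  xl <- array(0, c(1, 6, 6)); g <- array(0, c(1, 4, 4))
  expect_error(attention_gate(xl, g, p), "integer multiple")
})

test_that("whole-model gradients agree with finite differences", {
  set.seed(37)
  cfg <- model_config("attresunet", input_size = c(8, 8), input_channels = 3,
                      depth = 1, base_filters = 2)
  m <- build_model(cfg)
  x <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  y <- array(rbinom(8 * 8 * 2, 1, 0.4), c(8, 8, 1, 2))
  fw <- lesionseg:::model_forward(m, x, training = TRUE)
  dz <- lesionseg:::loss_grad_logits("bce", fw$p, y)
  gr <- lesionseg:::model_backward(m, fw$cache, dz)
  leaves <- list(list("enc", 1, "s1", "w"), list("enc", 1, "sc", "w"),
                 list("att", 1, "theta", "w"), list("att", 1, "psi", "b"),
                 list("up", 1, "gamma"), list("dec", 1, "s2", "w"),
                 list("head", "w"))
  get_leaf <- function(tr, pth) { for (k in pth) tr <- tr[[k]]; tr }
  eps <- 1e-6
  for (pth in leaves) {
    w <- get_leaf(m$weights, pth)
    g <- get_leaf(gr, pth)
    i <- sample(length(w), 1)
    lp <- lm <- NA
    for (s in c(1, -1)) {
      m2 <- m
      expr <- w; expr[i] <- expr[i] + s * eps
      assign_leaf <- function(tr, pth, v) {
        if (length(pth) == 1) { tr[[pth[[1]]]] <- v; return(tr) }
        tr[[pth[[1]]]] <- assign_leaf(tr[[pth[[1]]]], pth[-1], v)
        tr
      }
      m2$weights <- assign_leaf(m2$weights, pth, expr)
      p2 <- lesionseg:::model_forward(m2, x, training = TRUE)$p
      if (s == 1) lp <- bce_loss(p2, y) else lm <- bce_loss(p2, y)
    }
    fd <- (lp - lm) / (2 * eps)
    # absolute floor guards near-zero gradients and ReLU-kink noise in
    # the finite-difference estimate
    expect_lt(abs(g[i] - fd), 1e-5 + 1e-3 * abs(fd))
  }
})
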