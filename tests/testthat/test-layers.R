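# numerical differentiation helper (central differences)
num_grad <- function(f, x, h = 1e-3) {
  g <- if (is.null(dim(x))) numeric(length(x)) else array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

test_that("convolution matches a direct quadruple-loop oracle", {
  set.seed(101)
  x <- array(rnorm(9 * 9 * 3 * 2), c(9, 9, 3, 2))
  w <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  for (cfg in list(c(1, 1, 1), c(2, 1, 1), c(1, 2, 2), c(2, 0, 1), c(1, 3, 3))) {
    y <- museg:::cpp_conv2d_fw(x, w, b, cfg[1], cfg[2], cfg[3])
    ref <- conv_oracle(x, w, b, cfg[1], cfg[2], cfg[3])
    expect_equal(y, ref, tolerance = 1e-5,
                 label = paste("conv s/p/d", paste(cfg, collapse = "/")))
  }
})

test_that("convolution gradients agree with numerical differentiation", {
  set.seed(102)
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2, 1))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  dy <- array(rnorm(3 * 3 * 3), c(3, 3, 3, 1))
  loss <- function(x, w, b) sum(museg:::cpp_conv2d_fw(x, w, b, 2L, 1L, 1L) * dy)
  g <- museg:::cpp_conv2d_bw(x, w, dy, 2L, 1L, 1L, TRUE, TRUE)
  expect_lt(max(abs(g$dx - num_grad(function(z) loss(z, w, b), x))), 5e-3)
  expect_lt(max(abs(g$dw - num_grad(function(z) loss(x, z, b), w))), 5e-3)
  expect_lt(max(abs(g$db - num_grad(function(z) loss(x, w, z), b))), 5e-3)
  # cached-cols backward path computes the same gradients
  r <- museg:::cpp_conv2d_fw_cached(x, w, b, 2L, 1L, 1L)
  g2 <- museg:::cpp_conv2d_bw_cached(r$cols, dim(x), w, dy, 2L, 1L, 1L, TRUE, TRUE)
  expect_equal(g2$dw, g$dw, tolerance = 1e-6)
  expect_equal(g2$dx, g$dx, tolerance = 1e-6)
})

test_that("transposed convolution upsamples correctly and differentiates", {
  set.seed(103)
  x <- array(rnorm(5 * 5 * 4), c(5, 5, 4, 1))
  w <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))  # (kh, kw, Cout, Cin)
  b <- rnorm(3)
  y <- museg:::cpp_convt2d_fw(x, w, b, 2L, 1L, 1L)
  expect_identical(dim(y), c(10L, 10L, 3L, 1L))
  # adjoint identity: <convt(x), dy> = <x, conv-style backward of dy>
  dy <- array(rnorm(length(y)), dim(y))
  g <- museg:::cpp_convt2d_bw(x, w, dy, 2L, 1L, 1L, TRUE, TRUE)
  expect_equal(sum(y * dy) - sum(b * apply(dy, 3, sum)), sum(x * g$dx),
               tolerance = 1e-4)
  loss <- function(x, w, b) sum(museg:::cpp_convt2d_fw(x, w, b, 2L, 1L, 1L) * dy)
  expect_lt(max(abs(g$dx - num_grad(function(z) loss(z, w, b), x))), 5e-3)
  expect_lt(max(abs(g$dw - num_grad(function(z) loss(x, z, b), w))), 5e-3)
})

test_that("batch normalization normalizes and differentiates exactly", {
  set.seed(104)
  x <- array(rnorm(4 * 4 * 3 * 2, mean = 3, sd = 2), c(4, 4, 3, 2))
  gamma <- runif(3, 0.5, 1.5); beta <- rnorm(3)
  r <- museg:::cpp_bn_fw(x, gamma, beta, numeric(3), rep(1, 3), 0.1, 1e-5, TRUE)
  # per-channel output statistics: mean beta, sd gamma (up to eps)
  for (c in 1:3) {
    v <- as.vector(r$y[, , c, ])
    expect_equal(mean(v), beta[c], tolerance = 1e-6)
    expect_equal(stats::sd(v) * sqrt(31 / 32), gamma[c], tolerance = 1e-3)
  }
  dy <- array(rnorm(length(x)), dim(x))
  g <- museg:::cpp_bn_bw(x, gamma, r$mean, r$invstd, dy)
  bnloss <- function(x, ga, be) {
    sum(museg:::cpp_bn_fw(x, ga, be, numeric(3), rep(1, 3), 0.1, 1e-5, TRUE)$y * dy)
  }
  expect_lt(max(abs(g$dx - num_grad(function(z) bnloss(z, gamma, beta), x, 1e-4))), 1e-6)
  expect_lt(max(abs(g$dgamma - num_grad(function(z) bnloss(x, z, beta), gamma, 1e-4))), 1e-6)
  expect_lt(max(abs(g$dbeta - num_grad(function(z) bnloss(x, gamma, z), beta, 1e-4))), 1e-6)
  # eval mode uses the running statistics
  r2 <- museg:::cpp_bn_fw(x, gamma, beta, rep(0.5, 3), rep(2, 3), 0.1, 1e-5, FALSE)
  expect_equal(r2$y[1, 1, 1, 1],
               gamma[1] * (x[1, 1, 1, 1] - 0.5) / sqrt(2 + 1e-5) + beta[1],
               tolerance = 1e-10)
})

test_that("max pooling picks window maxima and routes gradients to them", {
  x <- array(0, c(4, 4, 1, 1))
  x[, , 1, 1] <- matrix(1:16, 4, 4)
  r <- museg:::cpp_maxpool_fw(x, 2L, 2L, 0L)
  expect_identical(dim(r$y), c(2L, 2L, 1L, 1L))
  expect_equal(as.vector(r$y), c(6, 8, 14, 16))
  dy <- r$y * 0 + 1
  dx <- museg:::cpp_maxpool_bw(r$idx, dy, dim(x))
  expect_equal(sum(dx), 4)
  expect_equal(dx[2, 2, 1, 1], 1)  # position of value 6
})

test_that("squeeze-excitation gating preserves shape, zeros and the bound", {
  set.seed(105)
  f <- array(rnorm(8 * 8 * 32 * 2), c(8, 8, 32, 2))
  g <- channel_attention(f, r = 16L)
  expect_identical(dim(g), dim(f))
  expect_true(all(abs(g) <= abs(f) + 1e-12))      # logistic gate < 1
  expect_true(all(channel_attention(f * 0, 16L) == 0))
  expect_error(channel_attention(f, r = 5L), "divisible")
})

test_that("squeeze-excitation backward matches numerical gradients", {
  set.seed(106)
  se <- museg:::new_se(8L, 4L)
  x <- array(rnorm(4 * 4 * 8 * 2), c(4, 4, 8, 2))
  dy <- array(rnorm(length(x)), dim(x))
  y <- se$fwd(x, TRUE)
  museg:::zero_grads(se)
  dx <- se$bwd(dy)
  loss_x <- function(z) sum(se$fwd(z, FALSE) * dy)
  expect_lt(max(abs(dx - num_grad(loss_x, x, 1e-4))), 1e-6)
  for (pt in c("w1", "b1", "w2", "b2")) {
    w0 <- get(pt, envir = se)
    lf <- function(z) { assign(pt, z, envir = se); on.exit(assign(pt, w0, envir = se))
      sum(se$fwd(x, FALSE) * dy) }
    expect_lt(max(abs(get(paste0("g", pt), envir = se) - num_grad(lf, w0, 1e-4))),
              1e-6, label = pt)
  }
})

test_that("composite blocks backpropagate correctly (directional derivatives)", {
  set.seed(107)
  cfg <- model_config(encoder_depth = 18L, dilation_rates = c(1L, 2L),
                      aspp_reduce = 8L, aspp_growth = 4L)
  m <- seg_model(cfg, seed = 3L)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  tgt <- array(rbinom(32 * 32, 1, 0.2), c(32, 32, 1, 1))
  # sum (not mean) BCE keeps gradient magnitudes well above the
  # single-precision forward noise
  loss_sum <- function() {
    length(tgt) * bce_loss(model_forward(m, x, training = TRUE), tgt)
  }
  p <- model_forward(m, x, training = TRUE)
  museg:::zero_grads(m)
  museg:::model_backward(m, p - tgt)
  layers <- museg:::collect_layers(m)
  pick <- c("encoder.stage2.b1.conv1", "bridge.branch2.atrous",
            "attention.skip2", "decoder.block3.up", "head.out",
            "encoder.stage1.b1.bn1")
  for (nm in pick) {
    l <- layers[[nm]]
    for (pt in l$ptensors) {
      w <- get(pt, envir = l)
      g <- get(paste0("g", pt), envir = l)
      gn <- sqrt(sum(g^2))
      if (gn < 1e-8) next
      u <- g / gn
      # per-tensor step targeting a fixed ~0.05 change in the loss: small
      # enough to stay within the local linear piece of the ReLU network,
      # large enough to rise above single-precision forward noise
      h <- 0.05 / gn
      assign(pt, w + h * u, envir = l); lp <- loss_sum()
      assign(pt, w - h * u, envir = l); lm <- loss_sum()
      assign(pt, w, envir = l)
      num <- (lp - lm) / (2 * h)
      expect_equal(num, gn, tolerance = 0.05,
                   label = paste("directional derivative along grad of", nm, pt))
    }
  }
})
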