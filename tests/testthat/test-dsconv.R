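test_that("quantization maps onto the signed b-bit grid and clamps", {
  expect_equal(quant_range(8), c(-128, 127))
  set.seed(21)
  for (b in c(2, 4, 8)) {
    w <- rnorm(257)
    wq <- quantize_vqk(w, quant_spec(bits = b))
    expect_true(all(wq >= -2^(b - 1) & wq <= 2^(b - 1) - 1))
    expect_true(is.integer(wq))
  }
})

test_that("weights already on the integer grid with unit scale are fixed points", {
  for (b in c(4, 8)) {
    qhi <- 2^(b - 1) - 1
    w <- c(sample(seq(-qhi, qhi), 20, replace = TRUE), qhi)
    wq <- quantize_vqk(w, quant_spec(bits = b))
    expect_equal(as.numeric(wq), w)
    expect_equal(attr(wq, "step"), 1)
  }
  # all-zero block: documented degenerate rule, step 1
  wq0 <- quantize_vqk(rep(0, 8), quant_spec(bits = 8))
  expect_equal(as.numeric(wq0), rep(0, 8))
  expect_equal(attr(wq0, "step"), 1)
})

test_that("kds fit matches the closed-form least squares", {
  f <- fit_kds(c(1, 2), c(2L, 4L), block_size = 2)
  expect_equal(f$scale, 0.5)   # sum(wq*w)/sum(wq^2) = 10/20
  expect_equal(f$bias, 0.0)    # exact reconstruction, zero residual
  # wq identical to w: scale 1, bias 0
  w <- rnorm(10)
  f2 <- fit_kds(w, w, block_size = 5)
  expect_equal(f2$scale, c(1, 1))
  expect_equal(f2$bias, c(0, 0), tolerance = 1e-12)
  # degenerate block of zero quantized weights
  f3 <- fit_kds(c(3, 5), c(0L, 0L), block_size = 2)
  expect_equal(f3$scale, 1)
  expect_equal(f3$bias, 4)
})

test_that("fitted kds scale is the residual minimizer on random blocks", {
  set.seed(22)
  for (i in 1:100) {
    n <- sample(4:64, 1)
    w <- rnorm(n, sd = runif(1, 0.1, 2))
    wq <- quantize_vqk(w, quant_spec(bits = sample(c(3, 4, 8), 1)))
    f <- fit_kds(w, wq, block_size = n)
    resid <- function(s) sum((as.numeric(wq) * s - w)^2)
    r0 <- resid(f$scale)
    expect_lte(r0, resid(f$scale * 1.1) + 1e-12)
    expect_lte(r0, resid(f$scale * 0.9) + 1e-12)
  }
})

test_that("quantize -> dequantize error is bounded by half a step", {
  set.seed(23)
  for (i in 1:20) {
    w <- rnorm(96)
    spec <- quant_spec(bits = 8, block_size = 32)
    wq <- quantize_vqk(w, spec)
    step <- attr(wq, "step")
    # raw linear map: per-weight error at most half a quantization step
    expect_lte(max(abs(as.numeric(wq) * step - w)), step / 2 + 1e-12)
    # the kds fit cannot worsen the summed squared reconstruction error
    deq <- dequantize_kds(wq, fit_kds(w, wq, spec$block_size))
    expect_lte(sum((deq - w)^2), sum((as.numeric(wq) * step - w)^2) + 1e-12)
  }
})

test_that("snake sample positions follow the serpentine rule", {
  sp <- snake_kernel_spec(3, offsets = 0)
  pos <- snake_sample_positions(c(5, 7), sp)
  expect_equal(pos$x, c(4, 5, 6))
  expect_equal(pos$y, c(7, 7, 7))
  sp2 <- snake_kernel_spec(3, offsets = c(0, 0.5, -0.5))
  pos2 <- snake_sample_positions(c(5, 7), sp2)
  expect_equal(pos2$x, c(4, 5, 6))
  expect_equal(pos2$y, c(7, 7.5, 6.5))
  # vertical axis swaps roles
  pos3 <- snake_sample_positions(c(5, 7), snake_kernel_spec(
    3, offsets = c(0.25, 0, 0), axis = "vertical"))
  expect_equal(pos3$x, c(5.25, 5, 5))
  expect_equal(pos3$y, c(6, 7, 8))
})

test_that("offsets are clamped to the configured bound", {
  sp <- snake_kernel_spec(3, offsets = c(2, -3, 0.4), offset_clamp = 1)
  expect_equal(sp$offsets, c(1, -1, 0.4))
  expect_error(snake_kernel_spec(4), "odd")
})

test_that("zero-offset snake convolution matches the dense oracle", {
  set.seed(24)
  for (i in 1:20) {
    C <- sample(1:3, 1); H <- sample(5:32, 1); W <- sample(5:32, 1)
    O <- sample(1:3, 1)
    x <- feature_map(array(rnorm(C * H * W), c(C, H, W)))
    w <- array(rnorm(O * C * 3), c(O, C, 3))
    b <- rnorm(O)
    horiz <- i %% 2 == 0
    out <- dsconv_apply(x, w, snake_kernel_spec(
      3, 0, axis = if (horiz) "horizontal" else "vertical"), bias = b)
    # dense kernel: 1x3 for horizontal taps, 3x1 for vertical
    wd <- if (horiz) array(w, c(O, C, 1, 3)) else
      array(aperm(array(w, c(O, C, 3, 1)), c(1, 2, 4, 3)), c(O, C, 3, 1))
    expect_lt(max(abs(out$values - dense_conv_oracle(x$values, wd, b))), 1e-5)
  }
})

test_that("bilinear sampling of a constant input stays constant", {
  x <- feature_map(array(2, c(1, 12, 12)))
  w <- array(1 / 3, c(1, 1, 3))
  out <- dsconv_apply(x, w, snake_kernel_spec(3, c(0.37, -0.61, 0.85)))
  # interior cells (away from the zero-padding border) keep the constant
  expect_equal(max(abs(out$values[1, 3:10, 3:10] - 2)), 0, tolerance = 1e-12)
})

test_that("weights representable at 8 bits survive the quantized path", {
  set.seed(25)
  step <- 0.013
  wq_true <- sample(-127:127, 2 * 3 * 3, replace = TRUE)
  wq_true[1] <- 127  # pin the range so the automatic step is recovered
  w <- array(step * wq_true, c(2, 3, 3))
  x <- feature_map(array(rnorm(3 * 10 * 10), c(3, 10, 10)))
  sp <- snake_kernel_spec(3, c(0.2, -0.4, 0.1))
  plain <- dsconv_apply(x, w, sp)
  quant <- dsconv_apply(x, w, sp, quant = quant_spec(bits = 8, block_size = 6))
  expect_lt(max(abs(plain$values - quant$values)), 1e-5)
})

test_that("dsconv_apply validates shapes", {
  x <- feature_map(array(0.5, c(2, 8, 8)))
  w <- array(0, c(1, 3, 3))
  expect_error(dsconv_apply(x, w, snake_kernel_spec(3)), "mismatch")
  expect_error(dsconv_apply(x, array(0, c(1, 2, 5)), snake_kernel_spec(3)),
               "tap count")
})

test_that("c2f block preserves spatial size and tracks parameter bookkeeping", {
  set.seed(26)
  x <- feature_map(array(rnorm(4 * 16 * 16), c(4, 16, 16)), stride = 4L)
  for (ds in c(TRUE, FALSE)) {
    blk <- c2f_block(4, 8, n = 1, dsconv = ds)
    out <- c2f_dsconv_forward(x, blk)
    expect_equal(dim(out$values), c(8, 16, 16))
    expect_equal(out$stride, 4L)
  }
  # n = 2 adds exactly one bottleneck's parameters
  b1 <- c2f_block(4, 8, n = 1, dsconv = TRUE)
  b2 <- c2f_block(4, 8, n = 2, dsconv = TRUE)
  h <- b1$hidden
  per_conv <- h * h * 3 + h + 3          # snake: weights + bias + offsets
  # cv2 input widens by h channels as well
  cv2_extra <- (3 * h - 2 * h) * 8 * 3
  expect_equal(n_params(b2) - n_params(b1), 2 * per_conv + cv2_extra)
  expect_error(c2f_dsconv_forward(feature_map(array(0, c(3, 8, 8))), b1),
               "mismatch")
})

test_that("c2f-dsconv receptive field grows as the dense composition predicts", {
  set.seed(27)
  blk <- c2f_block(1, 2, n = 1, dsconv = TRUE)
  # delta impulse at the center of a 13x13 map
  x <- array(0, c(1, 13, 13)); x[1, 7, 7] <- 1
  out <- c2f_dsconv_forward(feature_map(x), blk)
  on <- which(apply(abs(out$values) > 1e-12, c(2, 3), any), arr.ind = TRUE)
  # composition: cv1 (x +-1), bottleneck a (x +-1), b (y +-1), cv2 (y +-1)
  # -> support exactly rows 7 +- 2, cols 7 +- 2 for generic weights
  expect_equal(range(on[, 1]), c(5, 9))
  expect_equal(range(on[, 2]), c(5, 9))
})
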