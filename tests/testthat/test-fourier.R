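# Fourier blocks: FFT/IFFT utilities, amplitude/phase, conFFT, spectrum
# learning, multi-scale fusion and DConv, checked against brute-force DFT and
# naive convolution oracles.

ns <- asNamespace("dganet")

test_that("fft2d matches the constant-image and brute-force DFT oracles", {
  cimg <- matrix(3.5, 8, 8)
  s <- fft2d(cimg, full_spectrum = TRUE)
  amp <- sqrt(s$real^2 + s$imag^2)
  expect_equal(amp[1, 1, 1, 1], 64 * 3.5)
  expect_lt(max(amp[1, 1, 1, -1]), 1e-9)
  expect_lt(max(amp[1, 1, -1, ]), 1e-9)

  set.seed(1)
  x <- matrix(rnorm(64), 8, 8)
  s <- fft2d(x, full_spectrum = TRUE)
  oracle <- bf_dft2(x)
  expect_lt(max(abs(s$real[1, 1, , ] - Re(oracle))), 1e-8)
  expect_lt(max(abs(s$imag[1, 1, , ] - Im(oracle))), 1e-8)
  # Parseval: spatial energy = spectral energy / (H*W)
  expect_equal(sum(x^2), sum(Mod(oracle)^2) / 64, tolerance = 1e-4)
  expect_equal(sum(x^2), sum(s$real^2 + s$imag^2) / 64, tolerance = 1e-4)

  expect_error(fft2d(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
})

test_that("ifft2d inverts fft2d for full and half spectra", {
  set.seed(2)
  for (hw in list(c(16, 16), c(8, 12), c(7, 9))) {
    x <- array(rnorm(2 * 2 * hw[1] * hw[2]), c(2, 2, hw[1], hw[2]))
    expect_lt(max(abs(ifft2d(fft2d(x, full_spectrum = TRUE)) - x)), 1e-5)
    expect_lt(max(abs(ifft2d(fft2d(x)) - x)), 1e-5)
  }
  # DC-only spectrum of 64 on an 8x8 grid -> constant 1
  re <- array(0, c(1, 1, 8, 8))
  re[1, 1, 1, 1] <- 64
  im <- array(0, c(1, 1, 8, 8))
  y <- ifft2d(spectral_pair(re, im))
  expect_equal(as.vector(y), rep(1, 64), tolerance = 1e-9)
  # random spectrum vs the brute-force inverse oracle
  set.seed(3)
  rev <- matrix(rnorm(36), 6, 6)
  imv <- matrix(rnorm(36), 6, 6)
  sp <- spectral_pair(array(rev, c(1, 1, 6, 6)), array(imv, c(1, 1, 6, 6)))
  got <- ifft2d(sp)[1, 1, , ]
  want <- Re(bf_idft2(rev + 1i * imv))
  expect_lt(max(abs(got - want)), 1e-8)
  expect_error(spectral_pair(re, array(0, c(1, 1, 8, 4))), "share a shape")
})

test_that("amplitude_phase decomposes and reconstructs the spectrum", {
  re <- array(3, c(1, 1, 1, 1))
  im <- array(4, c(1, 1, 1, 1))
  ap <- amplitude_phase(spectral_pair(re, im))
  expect_equal(as.numeric(ap$amplitude), 5)
  expect_equal(as.numeric(ap$phase), atan(4 / 3), tolerance = 1e-4)
  z <- spectral_pair(array(0, c(1, 1, 2, 2)), array(0, c(1, 1, 2, 2)))
  apz <- amplitude_phase(z)
  expect_true(all(apz$amplitude == 0) && all(apz$phase == 0))
  set.seed(4)
  s <- fft2d(matrix(rnorm(64), 8, 8), full_spectrum = TRUE)
  ap <- amplitude_phase(s)
  expect_lt(max(abs(ap$amplitude * cos(ap$phase) - s$real)), 1e-6)
  expect_lt(max(abs(ap$amplitude * sin(ap$phase) - s$imag)), 1e-6)
})

test_that("conv_fft_block is identity/zero/oracle-consistent", {
  p <- make_conv_fft(1, 1)
  set.seed(5)
  x <- matrix(rnorm(64), 8, 8)
  set_parameter(p, "freq_conv.weight", 1)
  expect_lt(max(abs(conv_fft_block(x, p) - feature_map(x))), 1e-5)
  set_parameter(p, "freq_conv.weight", 0)
  expect_lt(max(abs(conv_fft_block(x, p))), 1e-12)

  # 2-channel random mix vs a spectral-domain oracle built on bf_dft2
  p2 <- make_conv_fft(2, 2)
  W <- matrix(rnorm(4, sd = 0.5), 2, 2) # (cin, cout)
  set_parameter(p2, "freq_conv.weight", as.vector(W))
  x2 <- rand_nchw(1, 2, 8, 8)
  got <- conv_fft_block(x2, p2)
  want <- array(0, dim(x2))
  spec <- list(bf_dft2(x2[1, 1, , ]), bf_dft2(x2[1, 2, , ]))
  for (co in 1:2) {
    mixed <- W[1, co] * spec[[1]] + W[2, co] * spec[[2]]
    want[1, co, , ] <- Re(bf_idft2(mixed))
  }
  expect_lt(max(abs(got - want)), 1e-4)
  expect_error(conv_fft_block(rand_nchw(1, 3, 8, 8), p2), "channel mismatch")
})

test_that("spectrum_learning honors the residual contract and the DFT oracle", {
  C <- 2
  p <- make_spectrum_learning(C)
  set.seed(6)
  x <- rand_nchw(1, C, 8, 8)
  # all non-residual paths zeroed -> exact identity
  fill_parameters(p, 0)
  expect_equal(unclass(spectrum_learning(x, p)), unclass(feature_map(x)))

  # identity 1x1 branches + zero 3x3: a nonnegative spectrum passes LeakyReLU
  # untouched, so the block is the identity (delta image -> all-ones real
  # spectrum, zero imaginary part)
  eye <- diag(C)
  for (nm in c("re1.weight", "re2.weight", "im1.weight", "im2.weight")) {
    set_parameter(p, nm, as.vector(eye))
  }
  delta <- array(0, c(1, C, 8, 8))
  delta[, , 1, 1] <- 2.5
  expect_lt(max(abs(spectrum_learning(delta, p) - delta)), 1e-5)

  # random parameters vs a step-by-step recomputation on the DFT oracle
  pr <- make_spectrum_learning(1)
  set.seed(7)
  for (nm in c("re1.weight", "re2.weight", "im1.weight", "im2.weight")) {
    set_parameter(pr, nm, rnorm(1, sd = 0.7))
  }
  k3 <- matrix(rnorm(9, sd = 0.4), 3, 3)
  b3 <- rnorm(1)
  set_parameter(pr, "post.weight", as.vector(k3))
  set_parameter(pr, "post.bias", b3)
  ps <- module_parameters(pr)
  leaky <- function(v) ifelse(v > 0, v, 0.01 * v)
  xm <- matrix(rnorm(64), 8, 8)
  Fo <- bf_dft2(xm)
  re_o <- as.numeric(ps$re2.weight$value) * leaky(as.numeric(ps$re1.weight$value) * Re(Fo))
  im_o <- as.numeric(ps$im2.weight$value) * leaky(as.numeric(ps$im1.weight$value) * Im(Fo))
  f_sp <- Re(bf_idft2(re_o + 1i * im_o))
  want <- naive_conv2(f_sp, k3) + b3 + xm
  got <- spectrum_learning(xm, pr)[1, 1, , ]
  expect_lt(max(abs(got - want)), 1e-4)
})

test_that("multiscale_fusion: residual identity, zero-input closed form, shapes", {
  C <- 1
  p <- make_multiscale_fusion(C)
  fill_parameters(p, 0)
  set_parameter(p, "bn1.gamma", 1)
  set_parameter(p, "bn2.gamma", 1)
  set.seed(8)
  x <- rand_nchw(1, C, 8, 8)
  expect_equal(unclass(multiscale_fusion(x, p)), unclass(feature_map(x)))

  # zero input, hand-computed constant response: conv bias b flows through
  # the (identity-statistics) BN, ReLU, and bilinear up/down unchanged
  p2 <- make_multiscale_fusion(1)
  fill_parameters(p2, 0)
  set_parameter(p2, "bn1.gamma", 1)
  set_parameter(p2, "bn2.gamma", 1)
  set_parameter(p2, "conv1.bias", 0.7)
  set_parameter(p2, "conv2.bias", -0.3)
  eps <- 1e-5
  want <- max(0, 0.7 / sqrt(1 + eps)) + max(0, -0.3 / sqrt(1 + eps)) # = 0.7/sqrt(1+eps)
  y <- multiscale_fusion(array(0, c(1, 1, 4, 4)), p2)
  expect_equal(as.vector(y), rep(want, 16), tolerance = 1e-9)

  p3 <- make_multiscale_fusion(8)
  x3 <- rand_nchw(2, 8, 16, 16)
  expect_identical(dim(multiscale_fusion(x3, p3)), dim(x3))
  expect_error(multiscale_fusion(rand_nchw(1, 8, 7, 8), p3), "downsamples")
})

test_that("dconv_block halves resolution and pools by window maximum", {
  p <- make_dconv(1, 4)
  y <- dconv_block(rand_nchw(1, 1, 8, 8), p)
  expect_identical(dim(unclass(y)), c(1L, 4L, 4L, 4L))

  # pooled output equals the direct window max of the pre-pool activation
  set.seed(9)
  x <- rand_nchw(1, 2, 8, 8)
  p2 <- make_dconv(2, 4)
  xt <- ns$tn_const(ns$as_hwcn(x))
  pre <- ns$no_grad(ns$with_training_mode(FALSE, {
    h <- ns$op_relu(ns$m_fwd(p2$children$bn1, ns$m_fwd(p2$children$conv1, xt)))
    ns$op_relu(ns$m_fwd(p2$children$bn2, ns$m_fwd(p2$children$conv2, h)))
  }))$value
  got <- ns$as_nchw(ns$no_grad(ns$m_fwd(p2, xt))$value)
  want <- array(0, c(1, 4, 4, 4))
  for (c in 1:4) {
    for (i in 1:4) {
      for (j in 1:4) {
        want[1, c, i, j] <- max(pre[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, 1])
      }
    }
  }
  expect_equal(got, want, tolerance = 1e-12)
  # constant-positive input: pooling equal values is a no-op on the value
  pc <- make_con_op(1, 3)
  xc <- array(1, c(1, 1, 6, 6))
  expect_identical(dim(unclass(con_op_block(xc, pc))), c(1L, 3L, 6L, 6L))
})

test_that("round-trip and residual-identity properties hold across sizes", {
  set.seed(10)
  for (i in 1:20) {
    h <- sample(c(4, 8, 16, 32, 64), 1)
    w <- sample(c(4, 8, 16, 32, 64), 1)
    x <- array(rnorm(h * w), c(1, 1, h, w))
    expect_lt(max(abs(ifft2d(fft2d(x)) - x)), 1e-5)
    s <- fft2d(x, full_spectrum = TRUE)
    expect_equal(sum(x^2), sum(s$real^2 + s$imag^2) / (h * w), tolerance = 1e-4)
  }
  # FSMF unit built from zeroed sub-blocks is the identity
  u <- make_fsmf_unit(4)
  fill_parameters(u, 0)
  set_parameter(u, "msf.bn1.gamma", 1)
  set_parameter(u, "msf.bn2.gamma", 1)
  x <- rand_nchw(1, 4, 8, 8)
  expect_equal(unclass(fsmf_unit(x, u)), unclass(feature_map(x)))
})

test_that("gradients reach every parameter of the FSMF unit", {
  u <- make_fsmf_unit(4)
  x <- ns$tn_const(array(rnorm(8 * 8 * 4), c(8, 8, 4, 1)))
  loss <- ns$with_training_mode(TRUE, {
    y <- ns$m_fwd(u, x)
    ns$op_mean(ns$op_mul(y, y))
  })
  ns$zero_grads(u)
  ns$tn_backward(loss)
  ps <- ns$module_parameters(u)
  for (nm in names(ps)) {
    expect_false(is.null(ps[[nm]]$grad), label = sprintf("grad of %s", nm))
    expect_true(all(is.finite(ps[[nm]]$grad)), label = sprintf("finite grad of %s", nm))
  }
})
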