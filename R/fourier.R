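# Fourier spectral blocks: FFT/IFFT utilities, amplitude/phase views, the
# conFFT stem, the spectrum-learning unit, the multi-scale fusion unit and
# the shared DConv / conOp convolutional blocks.
#
# Public functions speak (N, C, H, W) arrays; internally everything runs on
# the engine's (H, W, C, N) layout.

as_hwcn <- function(x) {
  if (is.matrix(x)) x <- array(x, c(1L, 1L, nrow(x), ncol(x)))
  stopifnot(length(dim(x)) == 4L)
  aperm(x, c(3L, 4L, 2L, 1L))
}

as_nchw <- function(v) aperm(v, c(4L, 3L, 1L, 2L))

#' Construct a feature map
#'
#' Validates a real-valued `(batch, channel, height, width)` array. A plain
#' matrix is promoted to a single-sample, single-channel map.
#'
#' @param data numeric array `(N, C, H, W)` or matrix `(H, W)`.
#' @return An object of class `feature_map` (the validated array).
#' @export
feature_map <- function(data) {
  if (is.matrix(data)) data <- array(data, c(1L, 1L, nrow(data), ncol(data)))
  if (length(dim(data)) != 4L) {
    stop("feature map must be a (batch, channel, height, width) array", call. = FALSE)
  }
  if (any(dim(data)[3:4] < 1L)) stop("spatial dimensions must be positive", call. = FALSE)
  stopifnot_finite(data, "feature map")
  structure(data, class = c("feature_map", "array"))
}

fm_data <- function(x) {
  if (inherits(x, "feature_map")) unclass(x) else feature_map(x)
}

# Run a block module on an (N, C, H, W) array in evaluation mode.
block_apply <- function(m, x) {
  v <- as_hwcn(fm_data(x))
  out <- no_grad(with_training_mode(FALSE, m_fwd(m, tn_const(v))))
  feature_map(as_nchw(out$value))
}

# ---- spectral pair -----------------------------------------------------------

#' Spectral pair of a 2D discrete Fourier transform
#'
#' Holds the real and imaginary parts of the slicewise 2D DFT of a feature
#' map, either as the full `W`-column spectrum or as the half-spectrum of a
#' real input (`W' = floor(W/2) + 1` columns plus conjugate symmetry).
#'
#' @param real,imag numeric arrays `(N, C, H, W')`.
#' @param full_spectrum logical; `TRUE` when `W' = W`.
#' @param width original image width (needed to invert a half-spectrum).
#' @return An object of class `spectral_pair`.
#' @export
spectral_pair <- function(real, imag, full_spectrum = TRUE, width = NULL) {
  if (!identical(dim(real), dim(imag))) {
    stop("real and imaginary parts must share a shape", call. = FALSE)
  }
  if (is.null(width)) {
    if (!full_spectrum) stop("half-spectrum pairs need the original width", call. = FALSE)
    width <- dim(real)[4L]
  }
  structure(list(real = real, imag = imag, full_spectrum = full_spectrum,
                 width = as.integer(width)),
            class = "spectral_pair")
}

#' 2D fast Fourier transform of a feature map
#'
#' Transforms each (sample, channel) slice to the frequency domain. The
#' default stores the half-spectrum of the real input; `full_spectrum = TRUE`
#' keeps all `W` columns (used by the brute-force DFT oracle tests).
#'
#' @param x feature map (`(N, C, H, W)` array or matrix).
#' @param full_spectrum keep the redundant conjugate half?
#' @return A [spectral_pair()].
#' @export
fft2d <- function(x, full_spectrum = FALSE) {
  v <- as_hwcn(fm_data(x))
  z <- fft2_raw(v)
  W <- dim(v)[2L]
  if (!full_spectrum) {
    keep <- seq_len(W %/% 2L + 1L)
    z <- z[, keep, , , drop = FALSE]
  }
  spectral_pair(as_nchw(Re(z)), as_nchw(Im(z)),
                full_spectrum = full_spectrum, width = W)
}

# Rebuild the full complex spectrum (H, W, C, N) from a spectral_pair.
full_spectrum_hwcn <- function(s) {
  z <- as_hwcn(s$real) + 1i * as_hwcn(s$imag)
  if (s$full_spectrum) return(z)
  d <- dim(z)
  H <- d[1L]; W <- s$width
  full <- array(0i, c(H, W, d[3L], d[4L]))
  full[, seq_len(d[2L]), , ] <- z
  for (w in seq.int(d[2L] + 1L, W)) {
    # conjugate symmetry of a real input: F(u, v) = Conj(F(-u mod H, -v mod W))
    src_w <- W - w + 2L
    src_h <- c(1L, rev(seq.int(2L, H)))
    full[, w, , ] <- Conj(z[src_h, src_w, , ])
  }
  full
}

#' Inverse 2D FFT of a spectral pair
#'
#' Recovers the spatial feature map; the imaginary residue of the numerical
#' inverse (below 1e-5 for valid pairs) is discarded.
#'
#' @param s a [spectral_pair()].
#' @return A [feature_map()].
#' @export
ifft2d <- function(s) {
  if (!inherits(s, "spectral_pair")) stop("ifft2d expects a spectral_pair", call. = FALSE)
  z <- full_spectrum_hwcn(s)
  d <- dim(z)
  y <- fft2_raw(z, inverse = TRUE) / (d[1L] * d[2L])
  feature_map(as_nchw(Re(y)))
}

#' Amplitude and phase of a spectrum
#'
#' Returns the polar decomposition: `amplitude = sqrt(re^2 + im^2)` and the
#' full-quadrant phase `atan2(im, re)`; zero-magnitude bins get phase 0.
#'
#' @param s a [spectral_pair()].
#' @return `list(amplitude =, phase =)`, arrays shaped like `s$real`.
#' @export
amplitude_phase <- function(s) {
  if (!inherits(s, "spectral_pair")) stop("amplitude_phase expects a spectral_pair", call. = FALSE)
  list(amplitude = sqrt(s$real^2 + s$imag^2), phase = atan2(s$imag, s$real))
}

# ---- block constructors ------------------------------------------------------

#' @rdname conv_fft_block
#' @param cin,cout input / output channel counts.
#' @export
make_conv_fft <- function(cin, cout) {
  conv <- layer_conv2d(cin, cout, k = 1L, bias = FALSE)
  new_module("conv_fft", children = list(freq_conv = conv), forward = function(m, x) {
    s <- op_fft2(x)
    # the same real 1x1 channel mix applies to both spectrum parts
    re <- m_fwd(m$children$freq_conv, s$re)
    im <- m_fwd(m$children$freq_conv, s$im)
    op_ifft2(re, im)
  })
}

#' conFFT block: FFT, 1x1 convolution in the frequency domain, inverse FFT
#'
#' The frequency-domain convolution is a channel mix applied identically to
#' the real and imaginary parts (a real linear map commutes with the DFT), so
#' an identity kernel makes the whole block the identity.
#'
#' @param x feature map.
#' @param p block created by `make_conv_fft()`.
#' @return A [feature_map()] of the same spatial size.
#' @export
conv_fft_block <- function(x, p) block_apply(p, x)

#' @rdname spectrum_learning
#' @param channels channel count (input and output).
#' @export
make_spectrum_learning <- function(channels) {
  ch <- list(
    re1 = layer_conv2d(channels, channels, k = 1L, bias = FALSE),
    re2 = layer_conv2d(channels, channels, k = 1L, bias = FALSE),
    im1 = layer_conv2d(channels, channels, k = 1L, bias = FALSE),
    im2 = layer_conv2d(channels, channels, k = 1L, bias = FALSE),
    post = layer_conv2d(channels, channels, k = 3L)
  )
  new_module("spectrum_learning", children = ch, forward = function(m, x) {
    s <- op_fft2(x)
    re <- m_fwd(m$children$re2, op_leaky_relu(m_fwd(m$children$re1, s$re)))
    im <- m_fwd(m$children$im2, op_leaky_relu(m_fwd(m$children$im1, s$im)))
    f <- op_ifft2(re, im)
    op_add(m_fwd(m$children$post, f), x)
  })
}

#' Fourier spectrum-learning unit
#'
#' Transforms the input to the frequency domain, passes the real and
#' imaginary parts through separate `1x1 conv -> LeakyReLU -> 1x1 conv`
#' branches, inverts the transform, applies a 3x3 convolution and adds the
#' residual input.
#'
#' @param x feature map.
#' @param p block created by `make_spectrum_learning()`.
#' @return A [feature_map()] of the input shape.
#' @export
spectrum_learning <- function(x, p) block_apply(p, x)

#' @rdname multiscale_fusion
#' @param channels channel count (input and output).
#' @export
make_multiscale_fusion <- function(channels) {
  ch <- list(
    conv1 = layer_conv2d(channels, channels, k = 3L),
    bn1 = layer_batchnorm(channels),
    conv2 = layer_conv2d(channels, channels, k = 3L),
    bn2 = layer_batchnorm(channels)
  )
  new_module("multiscale_fusion", children = ch, forward = function(m, x) {
    d <- dim(x$value)
    if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L) {
      stop("multiscale fusion needs even H and W: the second path downsamples by 2 and upsamples back",
           call. = FALSE)
    }
    ch1 <- op_relu(m_fwd(m$children$bn1, m_fwd(m$children$conv1, x)))
    dn <- op_avgpool2(x)
    ch2 <- op_upsample2(op_relu(m_fwd(m$children$bn2, m_fwd(m$children$conv2, dn))))
    op_add(op_add(ch1, ch2), x)
  })
}

#' Multi-scale fusion unit
#'
#' Fuses three paths by element-wise addition: a `3x3 conv + BN + ReLU` path
#' at native resolution, the same pipeline on a 2x-downsampled copy followed
#' by bilinear upsampling, and the residual input.
#'
#' @param x feature map; `H` and `W` must be even.
#' @param p block created by `make_multiscale_fusion()`.
#' @return A [feature_map()] of the input shape.
#' @export
multiscale_fusion <- function(x, p) block_apply(p, x)

#' @rdname dconv_block
#' @param cin,cout input channels / stage width.
#' @export
make_dconv <- function(cin, cout) {
  ch <- list(
    conv1 = layer_conv2d(cin, cout, k = 3L), bn1 = layer_batchnorm(cout),
    conv2 = layer_conv2d(cout, cout, k = 3L), bn2 = layer_batchnorm(cout)
  )
  new_module("dconv", children = ch, forward = function(m, x) {
    h <- op_relu(m_fwd(m$children$bn1, m_fwd(m$children$conv1, x)))
    h <- op_relu(m_fwd(m$children$bn2, m_fwd(m$children$conv2, h)))
    op_maxpool2(h)
  })
}

#' Double-convolution encoder block
#'
#' Two `3x3 conv + BN + ReLU` stages followed by 2x2 max-pooling (stride 2):
#' the output has the configured stage width and half the spatial size.
#'
#' @param x feature map; `H` and `W` must be even.
#' @param p block created by `make_dconv()`.
#' @return A [feature_map()] with halved spatial dimensions.
#' @export
dconv_block <- function(x, p) block_apply(p, x)

# Double conv without the trailing pool (branch stems, ablation stand-ins).
make_double_conv <- function(cin, cout) {
  ch <- list(
    conv1 = layer_conv2d(cin, cout, k = 3L), bn1 = layer_batchnorm(cout),
    conv2 = layer_conv2d(cout, cout, k = 3L), bn2 = layer_batchnorm(cout)
  )
  new_module("double_conv", children = ch, forward = function(m, x) {
    h <- op_relu(m_fwd(m$children$bn1, m_fwd(m$children$conv1, x)))
    op_relu(m_fwd(m$children$bn2, m_fwd(m$children$conv2, h)))
  })
}

#' @rdname con_op_block
#' @param cin,cout input / output channel counts.
#' @export
make_con_op <- function(cin, cout) {
  conv <- layer_conv2d(cin, cout, k = 3L)
  new_module("con_op", children = list(conv = conv), forward = function(m, x) {
    op_relu(m_fwd(m$children$conv, x))
  })
}

#' conOp block: 3x3 convolution plus ReLU
#'
#' @param x feature map.
#' @param p block created by `make_con_op()`.
#' @return A [feature_map()] of the same spatial size.
#' @export
con_op_block <- function(x, p) block_apply(p, x)

# FSMF unit = spectrum learning followed by multi-scale fusion.
make_fsmf <- function(channels) {
  ch <- list(spec = make_spectrum_learning(channels),
             msf = make_multiscale_fusion(channels))
  new_module("fsmf", children = ch, forward = function(m, x) {
    m_fwd(m$children$msf, m_fwd(m$children$spec, x))
  })
}

#' FSMF unit
#'
#' One Fourier spectral-learning multi-scale fusion unit: the spectrum
#' learning pass followed by the multi-scale fusion pass.
#'
#' @param x feature map with even `H`, `W`.
#' @param p block created by `make_fsmf_unit()`.
#' @return A [feature_map()] of the input shape.
#' @export
fsmf_unit <- function(x, p) block_apply(p, x)

#' @rdname fsmf_unit
#' @param channels channel count.
#' @export
make_fsmf_unit <- function(channels) make_fsmf(channels)
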