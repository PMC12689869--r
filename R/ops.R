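# Differentiable operations on (H, W, C, N) arrays.

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(sprintf("%s contains non-finite values", what), call. = FALSE)
}

# ---- element-wise ----------------------------------------------------------

op_add <- function(a, b) {
  tn_new(a$value + b$value, list(a, b), function(g) list(g, g))
}

op_sub <- function(a, b) {
  tn_new(a$value - b$value, list(a, b), function(g) list(g, -g))
}

op_mul <- function(a, b) {
  av <- a$value
  bv <- b$value
  count_mul(length(av))
  tn_new(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

op_scale <- function(a, s) {
  tn_new(a$value * s, list(a), function(g) list(g * s))
}

op_relu <- function(a) {
  m <- a$value > 0
  tn_new(a$value * m, list(a), function(g) list(g * m))
}

op_leaky_relu <- function(a, slope = 0.01) {
  v <- a$value
  m <- slope + (1 - slope) * (v > 0)
  tn_new(v * m, list(a), function(g) list(g * m))
}

op_gelu <- function(a) {
  # exact Gaussian form x * Phi(x)
  v <- a$value
  ph <- stats::pnorm(v)
  tn_new(v * ph, list(a), function(g) list(g * (ph + v * stats::dnorm(v))))
}

op_sum <- function(a) {
  d <- dim(a$value)
  tn_new(sum(a$value), list(a), function(g) list(array(as.numeric(g), d)))
}

op_mean <- function(a) {
  d <- dim(a$value)
  n <- length(a$value)
  tn_new(mean(a$value), list(a), function(g) list(array(as.numeric(g) / n, d)))
}

# ---- shape ------------------------------------------------------------------

op_permute <- function(a, perm) {
  inv <- order(perm)
  tn_new(aperm(a$value, perm), list(a), function(g) list(aperm(g, inv)))
}

op_reshape <- function(a, newdim) {
  olddim <- dim(a$value)
  v <- a$value
  dim(v) <- newdim
  tn_new(v, list(a), function(g) {
    dim(g) <- olddim
    list(g)
  })
}

# Extract a channel range (dim 3 of HWCN).
op_slice_c <- function(a, idx) {
  d <- dim(a$value)
  tn_new(a$value[, , idx, , drop = FALSE], list(a), function(g) {
    out <- array(0, d)
    out[, , idx, ] <- g
    list(out)
  })
}

# Concatenate along channels.
op_concat_c <- function(tensors) {
  vals <- lapply(tensors, function(t) t$value)
  d1 <- dim(vals[[1L]])
  cs <- vapply(vals, function(v) dim(v)[3L], 0)
  ctot <- sum(cs)
  out <- array(0, c(d1[1L], d1[2L], ctot, d1[4L]))
  off <- 0L
  for (i in seq_along(vals)) {
    out[, , off + seq_len(cs[i]), ] <- vals[[i]]
    off <- off + cs[i]
  }
  offs <- c(0L, cumsum(cs))
  tn_new(out, tensors, function(g) {
    lapply(seq_along(tensors), function(i) {
      g[, , (offs[i] + 1L):offs[i + 1L], , drop = FALSE]
    })
  })
}

# ---- matrix ops (2D values) -------------------------------------------------

op_matmul <- function(a, b) {
  av <- a$value
  bv <- b$value
  count_mul(nrow(av) * ncol(av) * ncol(bv))
  tn_new(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

op_slice_cols <- function(a, idx) {
  d <- dim(a$value)
  tn_new(a$value[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, d[1L], d[2L])
    out[, idx] <- g
    list(out)
  })
}

op_cbind <- function(tensors) {
  vals <- lapply(tensors, function(t) t$value)
  cs <- vapply(vals, ncol, 0L)
  offs <- c(0L, cumsum(cs))
  tn_new(do.call(cbind, vals), tensors, function(g) {
    lapply(seq_along(tensors), function(i) {
      g[, (offs[i] + 1L):offs[i + 1L], drop = FALSE]
    })
  })
}

# Row-wise softmax of a matrix (each row sums to one).
op_softmax_rows <- function(a) {
  v <- a$value
  mx <- col_max(t(v))
  e <- exp(v - mx)
  y <- e / rowSums(e)
  tn_new(y, list(a), function(g) {
    list(y * (g - rowSums(y * g)))
  })
}

# Column maxima of a matrix without apply() overhead: reduce over the
# (usually few) rows when the matrix is wide, over columns otherwise.
col_max <- function(m) {
  K <- nrow(m)
  M <- ncol(m)
  if (K <= M) {
    mx <- m[1L, ]
    if (K > 1L) for (i in 2:K) mx <- pmax(mx, m[i, ])
    mx
  } else {
    vapply(seq_len(M), function(j) max(m[, j]), 0)
  }
}

# Joint softmax over a set of array dimensions `dims`, independently for each
# index combination of the remaining dimensions.
op_softmax_dims <- function(a, dims) {
  v <- a$value
  nd <- length(dim(v))
  rest <- setdiff(seq_len(nd), dims)
  perm <- c(dims, rest)
  inv <- order(perm)
  K <- prod(dim(v)[dims])
  M <- prod(dim(v)[rest])
  pd <- dim(v)[perm]
  xp <- matrix(aperm(v, perm), K, M)
  mx <- col_max(xp)
  e <- exp(xp - rep(mx, each = K))
  s <- colSums(e)
  yp <- e / rep(s, each = K)
  ya <- yp
  dim(ya) <- pd
  y <- aperm(ya, inv)
  tn_new(y, list(a), function(g) {
    gp <- matrix(aperm(g, perm), K, M)
    dxp <- yp * (gp - rep(colSums(yp * gp), each = K))
    dim(dxp) <- pd
    list(aperm(dxp, inv))
  })
}

# ---- broadcast helpers ------------------------------------------------------

# Per-channel broadcast of a length-C vector over (H, W, C, N).
bc_channel <- function(v, d) {
  out <- rep(rep(v, each = d[1L] * d[2L]), times = d[4L])
  dim(out) <- d
  out
}

# Per-channel reduction (sum over H, W, N).
rd_channel <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1L] * d[2L], d[3L] * d[4L])
  rowSums(matrix(colSums(m), d[3L], d[4L]))
}

op_bias_c <- function(a, b) {
  d <- dim(a$value)
  tn_new(a$value + bc_channel(b$value, d), list(a, b), function(g) {
    list(g, rd_channel(g))
  })
}

# Add a learned plane p (2D) broadcast over the remaining dims of a 4D map.
# `axes` names the two array dims of `a` the plane spans, e.g. c(1, 2) for a
# (H, W) plane or c(3, 1) for a (C, H) plane.
op_add_plane <- function(a, p, axes) {
  d <- dim(a$value)
  nd <- 4L
  rest <- setdiff(seq_len(nd), axes)
  perm <- c(axes, rest)
  inv <- order(perm)
  pd <- d[perm]
  full <- aperm(array(as.numeric(p$value), pd), inv)
  tn_new(a$value + full, list(a, p), function(g) {
    gp <- matrix(aperm(g, perm), prod(d[axes]), prod(d[rest]))
    dp <- array(rowSums(gp), dim(p$value))
    list(g, dp)
  })
}

# ---- convolution ------------------------------------------------------------

# Stride-1 2D convolution with symmetric zero padding and dilation.
# x: (H, W, Cin, N); w: (kh, kw, Cin, Cout); b: length Cout or NULL.
op_conv2d <- function(x, w, b = NULL, pad = NULL, dil = 1L) {
  xv <- x$value
  wv <- w$value
  d <- dim(xv)
  kd <- dim(wv)
  if (kd[3L] != d[3L]) {
    stop(sprintf("channel mismatch: input has %d channels, kernel expects %d",
                 d[3L], kd[3L]), call. = FALSE)
  }
  kh <- kd[1L]; kw <- kd[2L]; cin <- kd[3L]; cout <- kd[4L]
  if (is.null(pad)) pad <- dil * (kh - 1L) %/% 2L
  H <- d[1L]; W <- d[2L]; N <- d[4L]
  count_mul(as.numeric(kh * kw * cin) * H * W * N * cout)
  one_by_one <- kh == 1L && kw == 1L && pad == 0L
  if (one_by_one) {
    ya <- conv1x1_fwd_cpp(xv, wv, H, W, cin, N, cout)
  } else {
    ya <- direct_conv_fwd_cpp(xv, wv, H, W, cin, N, kh, kw, cout, pad, dil)
  }
  dim(ya) <- c(H, W, cout, N)
  parents <- list(x, w)
  if (!is.null(b)) {
    ya <- ya + bc_channel(b$value, dim(ya))
    parents <- c(parents, list(b))
  }
  tn_new(ya, parents, function(g) {
    if (one_by_one) {
      bw <- conv1x1_bwd_cpp(xv, wv, g, H, W, cin, N, cout)
    } else {
      bw <- direct_conv_bwd_cpp(xv, wv, g, H, W, cin, N, kh, kw, cout, pad, dil)
    }
    dx <- bw$dx
    dim(dx) <- d
    dw <- bw$dw
    dim(dw) <- dim(wv)
    out <- list(dx, dw)
    if (!is.null(b)) out <- c(out, list(rd_channel(g)))
    out
  })
}

# ---- pooling / resizing -----------------------------------------------------

check_even <- function(d, what) {
  if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L) {
    stop(sprintf("%s requires even spatial dimensions for the 2x down/up path, got %dx%d",
                 what, d[1L], d[2L]), call. = FALSE)
  }
}

op_maxpool2 <- function(x) {
  v <- x$value
  d <- dim(v)
  check_even(d, "max-pooling")
  ro <- seq(1L, d[1L], 2L); re <- seq(2L, d[1L], 2L)
  co <- seq(1L, d[2L], 2L); ce <- seq(2L, d[2L], 2L)
  s <- list(
    v[ro, co, , , drop = FALSE], v[re, co, , , drop = FALSE],
    v[ro, ce, , , drop = FALSE], v[re, ce, , , drop = FALSE]
  )
  y <- pmax(s[[1L]], s[[2L]], s[[3L]], s[[4L]])
  tn_new(y, list(x), function(g) {
    dx <- array(0, d)
    taken <- array(FALSE, dim(y))
    m <- (s[[1L]] == y); dx[ro, co, , ] <- g * m; taken <- taken | m
    m <- (s[[2L]] == y) & !taken; dx[re, co, , ] <- g * m; taken <- taken | m
    m <- (s[[3L]] == y) & !taken; dx[ro, ce, , ] <- g * m; taken <- taken | m
    m <- (s[[4L]] == y) & !taken; dx[re, ce, , ] <- g * m
    list(dx)
  })
}

op_avgpool2 <- function(x) {
  v <- x$value
  d <- dim(v)
  check_even(d, "average pooling")
  ro <- seq(1L, d[1L], 2L); re <- seq(2L, d[1L], 2L)
  co <- seq(1L, d[2L], 2L); ce <- seq(2L, d[2L], 2L)
  y <- (v[ro, co, , , drop = FALSE] + v[re, co, , , drop = FALSE] +
          v[ro, ce, , , drop = FALSE] + v[re, ce, , , drop = FALSE]) / 4
  tn_new(y, list(x), function(g) {
    dx <- array(0, d)
    q <- g / 4
    dx[ro, co, , ] <- q; dx[re, co, , ] <- q
    dx[ro, ce, , ] <- q; dx[re, ce, , ] <- q
    list(dx)
  })
}

# Linear interpolation matrix (n_out x n_in), half-pixel centers
# (align_corners = FALSE), indices clamped at the borders.
resize_matrix <- function(n_in, n_out) {
  key <- sprintf("rs_%d_%d", n_in, n_out)
  m <- .dga$cache[[key]]
  if (!is.null(m)) return(m)
  m <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5 # 0-based source coordinate
    lo <- floor(src)
    t <- src - lo
    lo_c <- min(max(lo, 0), n_in - 1)
    hi_c <- min(max(lo + 1, 0), n_in - 1)
    m[i, lo_c + 1] <- m[i, lo_c + 1] + (1 - t)
    m[i, hi_c + 1] <- m[i, hi_c + 1] + t
  }
  .dga$cache[[key]] <- m
  m
}

# Apply a matrix along dim 1 (H) of an (H, W, C, N) tensor value.
apply_h <- function(v, M) {
  d <- dim(v)
  dim(v) <- c(d[1L], prod(d[-1L]))
  y <- M %*% v
  dim(y) <- c(nrow(M), d[-1L])
  y
}

apply_w <- function(v, M) {
  d <- dim(v)
  vp <- aperm(v, c(2L, 1L, 3L, 4L))
  dim(vp) <- c(d[2L], prod(d[-2L]))
  y <- M %*% vp
  dim(y) <- c(nrow(M), d[1L], d[3L], d[4L])
  aperm(y, c(2L, 1L, 3L, 4L))
}

# Bilinear resize to (h_out, w_out); differentiable and exact transpose in
# the backward pass.
op_resize_bilinear <- function(x, h_out, w_out) {
  v <- x$value
  d <- dim(v)
  Mh <- resize_matrix(d[1L], h_out)
  Mw <- resize_matrix(d[2L], w_out)
  y <- apply_w(apply_h(v, Mh), Mw)
  tn_new(y, list(x), function(g) {
    list(apply_w(apply_h(g, t(Mh)), t(Mw)))
  })
}

op_upsample2 <- function(x) {
  d <- dim(x$value)
  op_resize_bilinear(x, 2L * d[1L], 2L * d[2L])
}

# ---- normalization ----------------------------------------------------------

# Batch normalization over (H, W, N) per channel. `state` carries running
# statistics for evaluation mode; epsilon 1e-5, momentum 0.1.
op_batchnorm <- function(x, gamma, beta, state, eps = 1e-5, momentum = 0.1) {
  v <- x$value
  d <- dim(v)
  m <- d[1L] * d[2L] * d[4L]
  if (isTRUE(.dga$training)) {
    mu <- rd_channel(v) / m
    xc <- v - bc_channel(mu, d)
    va <- rd_channel(xc * xc) / m
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * va * m / max(m - 1, 1)
    inv <- 1 / sqrt(va + eps)
    xhat <- xc * bc_channel(inv, d)
    y <- xhat * bc_channel(gamma$value, d) + bc_channel(beta$value, d)
    tn_new(y, list(x, gamma, beta), function(g) {
      dgamma <- rd_channel(g * xhat)
      dbeta <- rd_channel(g)
      gmean <- bc_channel(dbeta / m, d)
      xmean <- bc_channel(dgamma / m, d)
      dx <- bc_channel(gamma$value * inv, d) * (g - gmean - xhat * xmean)
      list(dx, dgamma, dbeta)
    })
  } else {
    inv <- 1 / sqrt(state$running_var + eps)
    a <- gamma$value * inv
    y <- v * bc_channel(a, d) +
      bc_channel(beta$value - state$running_mean * a, d)
    tn_new(y, list(x, gamma, beta), function(g) {
      xhat <- (v - bc_channel(state$running_mean, d)) * bc_channel(inv, d)
      list(g * bc_channel(a, d), rd_channel(g * xhat), rd_channel(g))
    })
  }
}

# Layer normalization across channels at every spatial position.
op_layernorm_c <- function(x, gamma, beta, eps = 1e-5) {
  v <- x$value
  d <- dim(v)
  C <- d[3L]
  perm <- c(3L, 1L, 2L, 4L)
  inv_perm <- order(perm)
  xp <- matrix(aperm(v, perm), C)
  mu <- colMeans(xp)
  xc <- xp - rep(mu, each = C)
  va <- colMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * rep(inv, each = C)
  yp <- xhat * gamma$value + beta$value
  ya <- yp
  dim(ya) <- d[perm]
  y <- aperm(ya, inv_perm)
  tn_new(y, list(x, gamma, beta), function(g) {
    gp <- matrix(aperm(g, perm), C)
    dgamma <- rowSums(gp * xhat)
    dbeta <- rowSums(gp)
    gh <- gp * gamma$value
    dxp <- rep(inv, each = C) *
      (gh - rep(colMeans(gh), each = C) - xhat * rep(colMeans(gh * xhat), each = C))
    dim(dxp) <- d[perm]
    list(aperm(dxp, inv_perm), dgamma, dbeta)
  })
}

# ---- Fourier transforms -----------------------------------------------------

# 2D FFT over dims 1:2 of an (H, W, C, N) array; returns a complex array.
fft2_raw <- function(z, inverse = FALSE) {
  d <- dim(z)
  m <- stats::mvfft(matrix(z, d[1L], prod(d[-1L])), inverse = inverse)
  dim(m) <- d
  a <- aperm(m, c(2L, 1L, 3L, 4L))
  dim(a) <- c(d[2L], prod(d[-2L]))
  m2 <- stats::mvfft(a, inverse = inverse)
  dim(m2) <- c(d[2L], d[1L], d[3L], d[4L])
  aperm(m2, c(2L, 1L, 3L, 4L))
}

# Forward 2D DFT; returns list(re, im) tensor nodes.
op_fft2 <- function(x) {
  stopifnot_finite(x$value, "FFT input")
  z <- fft2_raw(x$value)
  re <- tn_new(Re(z), list(x), function(g) list(Re(fft2_raw(g, inverse = TRUE))))
  im <- tn_new(Im(z), list(x), function(g) list(-Im(fft2_raw(g, inverse = TRUE))))
  list(re = re, im = im)
}

# Inverse 2D DFT of a (re, im) pair; returns the real part (the imaginary
# residue of a numerically exact inverse is discarded).
op_ifft2 <- function(re, im) {
  d <- dim(re$value)
  hw <- d[1L] * d[2L]
  y <- Re(fft2_raw(re$value + 1i * im$value, inverse = TRUE)) / hw
  tn_new(y, list(re, im), function(g) {
    z <- fft2_raw(g)
    list(Re(z) / hw, Im(z) / hw)
  })
}
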