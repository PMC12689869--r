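# Multi-Axis Aggregation Hadamard Attention (MAHA).
#
# The block splits its input into four channel groups. Groups 1-3 receive
# Hadamard-product attention along one axis pair each (height-width,
# channel-height, channel-width) plus a residual connection; group 4 passes
# through a residual 3x3 convolution. The groups are concatenated and merged
# by a 3x3 convolution with exact-Gaussian GELU activation.
#
# Per-axis attention never materialises a token-by-token score matrix: the
# pre-activation map is the element-wise product of the q and k projections
# (with additive learned positional embeddings and a positional bias on the
# attended plane), normalised by a softmax over the attended axis pair, and
# used to modulate v element-wise. Cost is therefore linear in H*W.

#' Split a feature map into four channel groups
#'
#' Group `i` holds channels `[(i-1)C/4, iC/4)`; concatenating the groups in
#' order reproduces the input exactly.
#'
#' @param x feature map with channel count divisible by 4.
#' @return List of four [feature_map()]s.
#' @export
chunk4 <- function(x) {
  v <- fm_data(x)
  C <- dim(v)[2L]
  if (C %% 4L != 0L) {
    stop(sprintf("channel count %d is not divisible by 4", C), call. = FALSE)
  }
  g <- C %/% 4L
  lapply(0:3, function(i) feature_map(v[, i * g + seq_len(g), , , drop = FALSE]))
}

chunk4_nodes <- function(x) {
  C <- dim(x$value)[3L]
  if (C %% 4L != 0L) {
    stop(sprintf("channel count %d is not divisible by 4", C), call. = FALSE)
  }
  g <- C %/% 4L
  lapply(0:3, function(i) op_slice_c(x, i * g + seq_len(g)))
}

axis_dims <- function(axis) {
  switch(axis,
    "height-width" = c(1L, 2L),
    "channel-height" = c(3L, 1L),
    "channel-width" = c(3L, 2L),
    stop(sprintf("unknown attention axis '%s' (use height-width, channel-height or channel-width)",
                 axis), call. = FALSE)
  )
}

#' @rdname hadamard_axis_attention
#' @param channels group channel count.
#' @param axis attended axis pair: `"height-width"`, `"channel-height"` or
#'   `"channel-width"`.
#' @param plane_h,plane_w build-time spatial size of the attended maps; the
#'   positional tables are bilinearly rescaled if the runtime size differs.
#' @export
make_axis_attention <- function(channels, axis, plane_h, plane_w) {
  dims <- axis_dims(axis)
  plane_dim <- function(d) {
    c(if (3L %in% dims) channels else NULL,
      if (1L %in% dims) plane_h else NULL,
      if (2L %in% dims) plane_w else NULL)
  }
  pd <- plane_dim(dims)
  params <- list(
    pos_q = tn_param(rnorm_array(pd, sd = 0.02)),
    pos_k = tn_param(rnorm_array(pd, sd = 0.02)),
    pos_bias = tn_param(array(0, pd))
  )
  ch <- list(
    q = layer_conv2d(channels, channels, k = 1L),
    k = layer_conv2d(channels, channels, k = 1L),
    v = layer_conv2d(channels, channels, k = 1L)
  )
  fwd <- function(m, x) {
    d <- dim(x$value)
    q <- m_fwd(m$children$q, x)
    k <- m_fwd(m$children$k, x)
    v <- m_fwd(m$children$v, x)
    # rescale the positional tables when the runtime plane differs from the
    # build-time plane (tables are stored over the attended axes only)
    tables <- lapply(m$params[c("pos_q", "pos_k", "pos_bias")], function(p) {
      resize_plane(p, dims, d)
    })
    q <- op_add_plane(q, tables[[1L]], dims)
    k <- op_add_plane(k, tables[[2L]], dims)
    s <- op_add_plane(op_mul(q, k), tables[[3L]], dims)
    w <- op_softmax_dims(s, dims)
    op_mul(w, v)
  }
  new_module(paste0("axis_attention_", axis), forward = fwd,
             params = params, children = ch)
}

# Bilinearly rescale a stored positional table so its spatial axes match the
# runtime tensor dims `d`. Channel axes are never rescaled.
resize_plane <- function(p, dims, d) {
  pd <- dim(p$value)
  td <- d[dims]
  if (identical(as.integer(pd), as.integer(td))) return(p)
  v <- p$value
  for (i in seq_along(dims)) {
    if (dims[i] == 3L) {
      if (pd[i] != td[i]) stop("channel extent of positional table is fixed", call. = FALSE)
      next
    }
    M <- resize_matrix(dim(v)[i], td[i])
    v <- if (i == 1L) M %*% v else v %*% t(M)
  }
  Ms <- lapply(seq_along(dims), function(i) {
    if (dims[i] == 3L) diag(pd[i]) else resize_matrix(pd[i], td[i])
  })
  tn_new(v, list(p), function(g) {
    list(t(Ms[[1L]]) %*% g %*% Ms[[2L]])
  })
}

#' Hadamard-product attention along one axis pair
#'
#' Projects the input to q, k, v with 1x1 convolutions, forms the
#' element-wise pre-activation `q (*) k` plus learned positional terms,
#' normalises with a softmax over the attended axis pair (weights on that
#' axis sum to 1 at every position of the remaining axes) and modulates v
#' element-wise. No L-by-L score matrix is ever built, so the cost is linear
#' in the pixel count.
#'
#' @param x feature map (one channel group).
#' @param p block created by `make_axis_attention()`.
#' @return A [feature_map()] of the input shape.
#' @export
hadamard_axis_attention <- function(x, p) block_apply(p, x)

#' @rdname group4_conv
#' @param channels group channel count.
#' @export
make_group4_conv <- function(channels) {
  conv <- layer_conv2d(channels, channels, k = 3L)
  new_module("group4_conv", children = list(conv = conv), forward = function(m, x) {
    op_add(m_fwd(m$children$conv, x), x)
  })
}

#' Convolutional fourth group: residual 3x3 convolution
#'
#' @param x feature map (one channel group).
#' @param p block created by `make_group4_conv()`.
#' @return A [feature_map()]: `conv3x3(x) + x`.
#' @export
group4_conv <- function(x, p) block_apply(p, x)

#' @rdname maha_forward
#' @param cin,cout input / output channel counts (`cin` divisible by 4).
#' @param plane_h,plane_w build-time spatial size for the positional tables.
#' @export
make_maha <- function(cin, cout, plane_h, plane_w) {
  if (cin %% 4L != 0L) stop("MAHA input channels must be divisible by 4", call. = FALSE)
  g <- cin %/% 4L
  ch <- list(
    att1 = make_axis_attention(g, "height-width", plane_h, plane_w),
    att2 = make_axis_attention(g, "channel-height", plane_h, plane_w),
    att3 = make_axis_attention(g, "channel-width", plane_h, plane_w),
    g4 = make_group4_conv(g),
    merge = layer_conv2d(cin, cout, k = 3L)
  )
  new_module("maha", children = ch, forward = function(m, x) {
    gs <- chunk4_nodes(x)
    o1 <- op_add(m_fwd(m$children$att1, gs[[1L]]), gs[[1L]])
    o2 <- op_add(m_fwd(m$children$att2, gs[[2L]]), gs[[2L]])
    o3 <- op_add(m_fwd(m$children$att3, gs[[3L]]), gs[[3L]])
    o4 <- m_fwd(m$children$g4, gs[[4L]])
    op_gelu(m_fwd(m$children$merge, op_concat_c(list(o1, o2, o3, o4))))
  })
}

#' Full MAHA block forward pass
#'
#' Chunks the input into four channel groups, applies one-axis Hadamard
#' attention with a residual connection to groups 1-3 (height-width,
#' channel-height and channel-width respectively), a residual 3x3 convolution
#' to group 4, then concatenates, convolves 3x3 and applies GELU.
#'
#' @param x feature map with channels divisible by 4.
#' @param p block created by `make_maha()`.
#' @return A [feature_map()] with `cout` channels at the input size.
#' @export
maha_forward <- function(x, p) block_apply(p, x)
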