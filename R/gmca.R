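# Group Multi-Head Cross-Attention Aggregation (GMCA) decoder stage.
#
# Each stage receives the previous decoder output (upsampled 2x), the FSMF
# skip and the MAHA skip at the stage resolution. The three maps are chunked
# into four channel groups; matching groups are concatenated and layer
# normalised. The fused groups feed a four-branch dilated-convolution
# aggregation block (FFAB, dilations 1/2/5/7) while the three ungrouped maps
# feed a two-arm multi-head cross-attention block (MIAF). Both branch
# outputs are projected to the stage width by 1x1 convolutions and summed.

#' Bilinear 2x upsampling
#'
#' Half-pixel-centre (corner alignment disabled) bilinear interpolation that
#' doubles both spatial dimensions; constants are preserved exactly and the
#' spatial mean is preserved to numerical precision.
#'
#' @param x feature map.
#' @return A [feature_map()] with doubled `H` and `W`.
#' @export
upsample2x <- function(x) {
  v <- as_hwcn(fm_data(x))
  out <- no_grad(op_upsample2(tn_const(v)))
  feature_map(as_nchw(out$value))
}

#' @rdname group_fuse
#' @param c_gc,c_fl,c_mh channel counts of the decoder, FSMF and MAHA inputs
#'   (each divisible by 4).
#' @export
make_group_fuse <- function(c_gc, c_fl, c_mh) {
  cg <- (c_gc + c_fl + c_mh) %/% 4L
  ch <- list(ln1 = layer_layernorm(cg), ln2 = layer_layernorm(cg),
             ln3 = layer_layernorm(cg), ln4 = layer_layernorm(cg))
  new_module("group_fuse", children = ch, forward = function(m, up, fl, mh) {
    inputs <- list(up, fl, mh)
    inputs <- inputs[!vapply(inputs, is.null, FALSE)]
    dd <- lapply(inputs, function(t) dim(t$value))
    if (length(unique(lapply(dd, function(d) d[c(1L, 2L)]))) != 1L) {
      stop("group fusion inputs must share spatial dimensions", call. = FALSE)
    }
    gs <- lapply(inputs, chunk4_nodes)
    lapply(1:4, function(i) {
      cat_i <- op_concat_c(lapply(gs, `[[`, i))
      m_fwd(m$children[[i]], cat_i)
    })
  })
}

#' Three-way grouped fusion with layer normalization
#'
#' Chunks the upsampled decoder feature and the two encoder skips into four
#' channel groups each, concatenates matching groups along channels and layer
#' normalises every fused group (zero mean, unit variance over the
#' concatenated channels before the affine transform).
#'
#' @param up,fl,mh feature maps of equal spatial size: previous decoder
#'   output (upsampled), FSMF skip and MAHA skip.
#' @param p block created by `make_group_fuse()`.
#' @return List of four fused [feature_map()]s.
#' @export
group_fuse <- function(up, fl, mh, p) {
  ins <- lapply(list(up, fl, mh), function(x) tn_const(as_hwcn(fm_data(x))))
  out <- no_grad(with_training_mode(FALSE, m_fwd(p, ins[[1L]], ins[[2L]], ins[[3L]])))
  lapply(out, function(t) feature_map(as_nchw(t$value)))
}

#' @rdname ffab
#' @param channels per-group channel count.
#' @export
make_ffab <- function(channels) {
  dil <- c(1L, 2L, 5L, 7L)
  ch <- lapply(dil, function(d) layer_conv2d(channels, channels, k = 3L, dil = d))
  names(ch) <- sprintf("dil%d", dil)
  new_module("ffab", children = ch, forward = function(m, groups) {
    if (length(groups) != 4L) {
      stop(sprintf("FFAB expects 4 fused groups, got %d", length(groups)), call. = FALSE)
    }
    op_concat_c(lapply(1:4, function(i) m_fwd(m$children[[i]], groups[[i]])))
  })
}

#' Four-branch dilated-convolution aggregation (FFAB)
#'
#' Group `i` passes through a size-preserving 3x3 convolution with dilation
#' `d_i` in (1, 2, 5, 7) (padding `d_i`); the four outputs are concatenated
#' along channels.
#'
#' @param groups list of four equal-shape feature maps.
#' @param p block created by `make_ffab()`.
#' @return A [feature_map()] with four times the group channel count.
#' @export
ffab <- function(groups, p) {
  gs <- lapply(groups, function(g) tn_const(as_hwcn(fm_data(g))))
  out <- no_grad(with_training_mode(FALSE, m_fwd(p, gs)))
  feature_map(as_nchw(out$value))
}

#' @rdname miaf
#' @param c_up,c_kv channel counts of the query map and of the two key/value
#'   maps.
#' @param embed_dim total embedding dimension `D` (divisible by `heads`).
#' @param heads head count `H`.
#' @param token_budget maximum token count before attention; larger maps are
#'   average-pooled to the budget and bilinearly restored afterwards.
#' @param combine `"add"` (element-wise addition of the two arms) or
#'   `"concat"` (channel concatenation followed by a 1x1 convolution).
#' @export
make_miaf <- function(c_up, c_kv, embed_dim, heads = 4L, token_budget = 4096L,
                      combine = c("add", "concat"), single_arm = FALSE) {
  combine <- match.arg(combine)
  if (embed_dim %% heads != 0L) {
    stop(sprintf("embedding dimension %d is not divisible by %d heads",
                 embed_dim, heads), call. = FALSE)
  }
  ch <- list(
    q_mh = layer_conv2d(c_up, embed_dim, k = 1L),
    k_mh = layer_conv2d(c_kv, embed_dim, k = 1L),
    v_mh = layer_conv2d(c_kv, embed_dim, k = 1L)
  )
  if (!single_arm) {
    ch$q_fl <- layer_conv2d(c_up, embed_dim, k = 1L)
    ch$k_fl <- layer_conv2d(c_kv, embed_dim, k = 1L)
    ch$v_fl <- layer_conv2d(c_kv, embed_dim, k = 1L)
    if (combine == "concat") {
      ch$combine <- layer_conv2d(2L * embed_dim, embed_dim, k = 1L)
    }
  }
  fwd <- function(m, up, fl, mh) {
    d <- dim(up$value)
    H <- d[1L]; W <- d[2L]; N <- d[4L]
    # token-budget pooling: halve the attention grid until it fits
    ah <- H; aw <- W
    while (ah * aw > token_budget && ah %% 2L == 0L && aw %% 2L == 0L) {
      ah <- ah %/% 2L; aw <- aw %/% 2L
    }
    pool <- function(t) {
      while (dim(t$value)[1L] > ah) t <- op_avgpool2(t)
      t
    }
    up_p <- pool(up)
    arm <- function(qmod, kmod, vmod, src) {
      # pooling first keeps the projections on the attention grid
      q <- m_fwd(qmod, up_p)
      k <- m_fwd(kmod, pool(src))
      v <- m_fwd(vmod, pool(src))
      attend_tokens(q, k, v, heads)
    }
    a1 <- if (!single_arm && !is.null(fl)) {
      arm(m$children$q_fl, m$children$k_fl, m$children$v_fl, fl)
    } else {
      NULL
    }
    a2 <- arm(m$children$q_mh, m$children$k_mh, m$children$v_mh, mh)
    out <- if (is.null(a1)) {
      a2
    } else if (combine == "add") {
      op_add(a1, a2)
    } else {
      m_fwd(m$children$combine, op_concat_c(list(a1, a2)))
    }
    if (ah != H || aw != W) out <- op_resize_bilinear(out, H, W)
    out
  }
  new_module("miaf", children = ch, forward = fwd)
}

# Scaled dot-product multi-head attention over flattened spatial tokens.
# q, k, v: (H, W, D, N) tensors with D divisible by `heads`.
attend_tokens <- function(q, k, v, heads) {
  d <- dim(q$value)
  L <- d[1L] * d[2L]
  D <- d[3L]
  N <- d[4L]
  dh <- D %/% heads
  scale <- 1 / sqrt(D / heads)
  outs <- vector("list", N)
  for (n in seq_len(N)) {
    qm <- op_reshape(op_slice_n(q, n), c(L, D))
    km <- op_reshape(op_slice_n(k, n), c(L, D))
    vm <- op_reshape(op_slice_n(v, n), c(L, D))
    head_out <- vector("list", heads)
    for (h in seq_len(heads)) {
      idx <- (h - 1L) * dh + seq_len(dh)
      qh <- op_slice_cols(qm, idx)
      kh <- op_slice_cols(km, idx)
      vh <- op_slice_cols(vm, idx)
      score <- op_scale(op_matmul(qh, op_transpose(kh)), scale)
      head_out[[h]] <- op_matmul(op_softmax_rows(score), vh)
    }
    outs[[n]] <- op_reshape(op_cbind(head_out), c(d[1L], d[2L], D, 1L))
  }
  op_concat_n(outs)
}

op_transpose <- function(a) {
  tn_new(t(a$value), list(a), function(g) list(t(g)))
}

op_slice_n <- function(a, n) {
  d <- dim(a$value)
  tn_new(a$value[, , , n, drop = FALSE], list(a), function(g) {
    out <- array(0, d)
    out[, , , n] <- g
    list(out)
  })
}

op_concat_n <- function(tensors) {
  vals <- lapply(tensors, function(t) t$value)
  d1 <- dim(vals[[1L]])
  N <- length(vals)
  out <- array(0, c(d1[1L], d1[2L], d1[3L], N))
  for (i in seq_len(N)) out[, , , i] <- vals[[i]]
  tn_new(out, tensors, function(g) {
    lapply(seq_len(N), function(i) g[, , , i, drop = FALSE])
  })
}

#' Multi-head interactive attention fusion (MIAF)
#'
#' Two cross-attention arms over flattened spatial tokens: arm 1 takes its
#' queries from the upsampled decoder feature and keys/values from the FSMF
#' skip, arm 2 queries the same decoder feature against the MAHA skip. Each
#' arm is standard multi-head scaled dot-product attention
#' (`softmax(Q K^T / sqrt(D/H)) V`, rows summing to 1); the arms are combined
#' element-wise.
#'
#' @param up,fl,mh feature maps of equal spatial size.
#' @param p block created by `make_miaf()`.
#' @return A [feature_map()] with `embed_dim` channels.
#' @export
miaf <- function(up, fl, mh, p) {
  ins <- lapply(list(up, fl, mh), function(x) tn_const(as_hwcn(fm_data(x))))
  out <- no_grad(with_training_mode(FALSE, m_fwd(p, ins[[1L]], ins[[2L]], ins[[3L]])))
  feature_map(as_nchw(out$value))
}

#' @rdname gmca_forward
#' @param c_prev,c_skip channel counts of the previous decoder output and of
#'   each encoder skip.
#' @param width output stage width.
#' @param heads,token_budget,combine see [make_miaf()].
#' @param upsample logical: upsample the decoder input 2x first (FALSE for
#'   the bottleneck stage).
#' @param single_branch drop the FSMF skip (branch-ablation variant).
#' @export
make_gmca <- function(c_prev, c_skip, width, heads = 4L, token_budget = 4096L,
                      combine = "add", upsample = TRUE, single_branch = FALSE) {
  n_in <- if (single_branch) 2L else 3L
  c_cat <- c_prev + (n_in - 1L) * c_skip
  ch <- list(
    fuse = make_group_fuse(c_prev, if (single_branch) 0L else c_skip, c_skip),
    ffab = make_ffab(c_cat %/% 4L),
    miaf = make_miaf(c_prev, c_skip, width, heads, token_budget, combine,
                     single_arm = single_branch),
    proj_ffab = layer_conv2d(c_cat, width, k = 1L),
    proj_miaf = layer_conv2d(width, width, k = 1L)
  )
  new_module("gmca", children = ch, forward = function(m, prev, fl, mh) {
    up <- if (upsample) op_upsample2(prev) else prev
    groups <- m_fwd(m$children$fuse, up, fl, mh)
    fa <- m_fwd(m$children$ffab, groups)
    at <- m_fwd(m$children$miaf, up, fl, mh)
    op_add(m_fwd(m$children$proj_ffab, fa), m_fwd(m$children$proj_miaf, at))
  })
}

#' Full GMCA decoder stage
#'
#' Upsamples the previous decoder output, fuses it with the two encoder
#' skips through grouped layer-normalised concatenation, runs the FFAB and
#' MIAF branches in parallel, projects each to the stage width with a 1x1
#' convolution and sums them.
#'
#' @param prev,fl,mh previous decoder output and the FSMF / MAHA skips; after
#'   upsampling all three must share spatial dimensions.
#' @param p block created by `make_gmca()`.
#' @return A [feature_map()] at the skip resolution with `width` channels.
#' @export
gmca_forward <- function(prev, fl, mh, p) {
  ins <- lapply(list(prev, fl, mh), function(x) tn_const(as_hwcn(fm_data(x))))
  out <- no_grad(with_training_mode(FALSE, m_fwd(p, ins[[1L]], ins[[2L]], ins[[3L]])))
  feature_map(as_nchw(out$value))
}
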