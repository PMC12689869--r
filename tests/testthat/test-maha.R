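# Multi-axis Hadamard attention: grouping, per-axis attention vs a literal
# loop oracle, the convolutional fourth group, the merged block, and the
# linear-cost property.

ns <- asNamespace("dganet")

test_that("chunk4 is a lossless, layout-stable partition", {
  set.seed(20)
  x <- rand_nchw(2, 8, 4, 4)
  gs <- chunk4(x)
  expect_length(gs, 4L)
  expect_identical(dim(unclass(gs[[1]]))[2], 2L)
  recon <- array(0, dim(x))
  for (i in 1:4) recon[, (2 * i - 1):(2 * i), , ] <- gs[[i]]
  expect_identical(recon, unclass(feature_map(x)))
  expect_error(chunk4(rand_nchw(1, 6, 4, 4)), "divisible by 4")
  # channels labeled 0..7: the last group holds channels {6, 7}
  lab <- array(rep(0:7, each = 16), c(4, 4, 8, 1))
  lab <- aperm(lab, c(4, 3, 1, 2))
  g4 <- chunk4(lab)[[4]]
  expect_setequal(unique(as.vector(unclass(g4))), c(6, 7))
})

test_that("hadamard axis attention: zero map, uniform softmax, loop oracle", {
  # all parameters zero -> v = 0 -> output 0
  p <- make_axis_attention(2, "height-width", 4, 4)
  fill_parameters(p, 0)
  x <- rand_nchw(1, 2, 4, 4)
  expect_lt(max(abs(hadamard_axis_attention(x, p))), 1e-12)

  # zero q/k and identity v: softmax of zeros is uniform (1/n, n = 4 on 2x2)
  p2 <- make_axis_attention(1, "height-width", 2, 2)
  fill_parameters(p2, 0)
  set_parameter(p2, "v.weight", 1)
  x2 <- array(c(1, 2, 3, 4), c(1, 1, 2, 2))
  expect_equal(as.vector(unclass(hadamard_axis_attention(x2, p2))),
               as.vector(unclass(feature_map(x2))) / 4, tolerance = 1e-12)

  # random parameters vs a literal project -> Hadamard -> bias -> softmax ->
  # modulate loop for each axis
  set.seed(21)
  for (axis in c("height-width", "channel-height", "channel-width")) {
    C <- 2
    p3 <- make_axis_attention(C, axis, 4, 4)
    for (prm in names(ns$module_parameters(p3))) {
      v <- ns$module_parameters(p3)[[prm]]
      set_parameter(p3, prm, rnorm(length(v$value), sd = 0.5))
    }
    x3 <- rand_nchw(2, C, 4, 4)
    got <- unclass(hadamard_axis_attention(x3, p3))

    ps <- ns$module_parameters(p3)
    proj <- function(which, xa) {
      w <- ps[[paste0(which, ".weight")]]$value # (1,1,C,C)
      b <- ps[[paste0(which, ".bias")]]$value
      out <- array(0, dim(xa))
      for (n in 1:dim(xa)[1]) for (co in 1:C) {
        acc <- matrix(b[co], dim(xa)[3], dim(xa)[4])
        for (ci in 1:C) acc <- acc + w[1, 1, ci, co] * xa[n, ci, , ]
        out[n, co, , ] <- acc
      }
      out
    }
    q <- proj("q", x3); k <- proj("k", x3); v <- proj("v", x3)
    # positional terms broadcast over the non-attended dims; tables are
    # (H, W), (C, H) or (C, W) for the three axes
    pq <- ps$pos_q$value; pk <- ps$pos_k$value; rb <- ps$pos_bias$value
    add_plane <- function(arr, pl) {
      out <- arr
      for (n in 1:dim(arr)[1]) for (c in 1:C) for (i in 1:dim(arr)[3]) for (j in 1:dim(arr)[4]) {
        out[n, c, i, j] <- arr[n, c, i, j] + switch(axis,
          "height-width" = pl[i, j],
          "channel-height" = pl[c, i],
          "channel-width" = pl[c, j])
      }
      out
    }
    # s = (q + Pq) (*) (k + Pk) + rb
    s <- add_plane(q, pq) * add_plane(k, pk) + add_plane(array(0, dim(q)), rb)
    # softmax over the attended axis pair, per remaining index
    w_att <- array(0, dim(s))
    d <- dim(s)
    if (axis == "height-width") {
      for (n in 1:d[1]) for (c in 1:C) {
        e <- exp(s[n, c, , ] - max(s[n, c, , ]))
        w_att[n, c, , ] <- e / sum(e)
      }
    } else if (axis == "channel-height") {
      for (n in 1:d[1]) for (j in 1:d[4]) {
        e <- exp(s[n, , , j] - max(s[n, , , j]))
        w_att[n, , , j] <- e / sum(e)
      }
    } else {
      for (n in 1:d[1]) for (i in 1:d[3]) {
        e <- exp(s[n, , i, ] - max(s[n, , i, ]))
        w_att[n, , i, ] <- e / sum(e)
      }
    }
    want <- w_att * v
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("group4_conv is a residual 3x3 convolution", {
  p <- make_group4_conv(2)
  fill_parameters(p, 0)
  set.seed(22)
  g <- rand_nchw(1, 2, 4, 4)
  expect_equal(unclass(group4_conv(g, p)), unclass(feature_map(g)))
  set_parameter(p, "conv.bias", c(0.5, -1))
  z <- array(0, c(1, 2, 4, 4))
  out <- unclass(group4_conv(z, p))
  expect_equal(unique(as.vector(out[, 1, , ])), 0.5)
  expect_equal(unique(as.vector(out[, 2, , ])), -1)
  # random parameters vs the naive convolution oracle
  k <- array(rnorm(3 * 3 * 2 * 2, sd = 0.4), c(3, 3, 2, 2))
  b <- rnorm(2)
  set_parameter(p, "conv.weight", as.vector(k))
  set_parameter(p, "conv.bias", b)
  want <- naive_conv_nchw(g, k, b) + g
  expect_lt(max(abs(unclass(group4_conv(g, p)) - want)), 1e-10)
})

test_that("maha_forward composes the groups per the block contract", {
  p <- make_maha(8, 8, 4, 4)
  fill_parameters(p, 0)
  x <- rand_nchw(1, 8, 4, 4)
  expect_lt(max(abs(maha_forward(x, p))), 1e-12) # GELU(0) = 0

  # zeroed attention/conv sub-blocks + identity merge -> GELU(x)
  p2 <- make_maha(8, 8, 4, 4)
  fill_parameters(p2, 0)
  eye <- diag(8)
  w <- array(0, c(3, 3, 8, 8))
  w[2, 2, , ] <- eye
  set_parameter(p2, "merge.weight", as.vector(w))
  got <- unclass(maha_forward(x, p2))
  want <- x * pnorm(x)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("MAHA multiply count scales linearly with pixel count", {
  p <- make_maha(8, 8, 16, 16)
  count_at <- function(hw) {
    x <- ns$tn_const(array(0, c(hw, hw, 8, 1)))
    ns$with_mul_counter(ns$no_grad(ns$with_training_mode(FALSE, ns$m_fwd(p, x))))
  }
  c16 <- count_at(16)
  c32 <- count_at(32)
  expect_gt(c16, 0)
  expect_lt(abs(c32 / c16 - 4), 0.05 * 4)
})

test_that("gradients reach every MAHA parameter, including positional tables", {
  p <- make_maha(8, 8, 4, 4)
  x <- ns$tn_const(array(rnorm(4 * 4 * 8), c(4, 4, 8, 1)))
  loss <- ns$with_training_mode(TRUE, {
    y <- ns$m_fwd(p, x)
    ns$op_mean(ns$op_mul(y, y))
  })
  ns$zero_grads(p)
  ns$tn_backward(loss)
  ps <- ns$module_parameters(p)
  for (nm in names(ps)) {
    expect_false(is.null(ps[[nm]]$grad), label = sprintf("grad of %s", nm))
  }
})
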