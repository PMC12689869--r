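# Independent oracles used by the DERIVED-value tests. These are deliberately
# naive (double loops, all-pairs scans) and never share code with the
# implementation paths they check.

# Brute-force O(N^4) 2D DFT of a matrix: F(u,v) = sum f(x,y) exp(-2i pi (...)).
bf_dft2 <- function(f) {
  H <- nrow(f); W <- ncol(f)
  out <- matrix(0i, H, W)
  for (u in 0:(H - 1)) {
    for (v in 0:(W - 1)) {
      acc <- 0i
      for (x in 0:(H - 1)) {
        for (y in 0:(W - 1)) {
          acc <- acc + f[x + 1, y + 1] * exp(-2i * pi * (u * x / H + v * y / W))
        }
      }
      out[u + 1, v + 1] <- acc
    }
  }
  out
}

# Brute-force inverse DFT (with the 1/(H*W) normalization).
bf_idft2 <- function(Fm) {
  H <- nrow(Fm); W <- ncol(Fm)
  out <- matrix(0i, H, W)
  for (x in 0:(H - 1)) {
    for (y in 0:(W - 1)) {
      acc <- 0i
      for (u in 0:(H - 1)) {
        for (v in 0:(W - 1)) {
          acc <- acc + Fm[u + 1, v + 1] * exp(2i * pi * (u * x / H + v * y / W))
        }
      }
      out[x + 1, y + 1] <- acc / (H * W)
    }
  }
  out
}

# Naive size-preserving 2D convolution (stride 1, zero padding, dilation) of
# a single-channel matrix with one kernel tap grid.
naive_conv2 <- function(x, k, dil = 1L) {
  H <- nrow(x); W <- ncol(x)
  kh <- nrow(k); kw <- ncol(k)
  pad <- dil * (kh - 1L) %/% 2L
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      acc <- 0
      for (a in seq_len(kh)) {
        for (b in seq_len(kw)) {
          ii <- i + (a - 1L) * dil - pad
          jj <- j + (b - 1L) * dil - pad
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
            acc <- acc + k[a, b] * x[ii, jj]
          }
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Multi-channel naive convolution on an (N, C, H, W) array with a
# (kh, kw, cin, cout) kernel and per-output-channel bias.
naive_conv_nchw <- function(x, w, b = NULL, dil = 1L) {
  d <- dim(x)
  cout <- dim(w)[4L]
  out <- array(0, c(d[1L], cout, d[3L], d[4L]))
  for (n in seq_len(d[1L])) {
    for (co in seq_len(cout)) {
      acc <- matrix(if (is.null(b)) 0 else b[co], d[3L], d[4L])
      for (ci in seq_len(d[2L])) {
        acc <- acc + naive_conv2(x[n, ci, , ], w[, , ci, co], dil)
      }
      out[n, co, , ] <- acc
    }
  }
  out
}

# All-pairs directed surface distances: for every boundary pixel of `from`,
# the minimum spacing-scaled Euclidean distance to any boundary pixel of `to`.
allpairs_directed <- function(from, to, spacing) {
  bf_ <- which(oracle_boundary(from), arr.ind = TRUE)
  bt_ <- which(oracle_boundary(to), arr.ind = TRUE)
  nd <- ncol(bf_)
  sp <- rep(spacing, length.out = nd)
  vapply(seq_len(nrow(bf_)), function(i) {
    diffs <- sweep(bt_, 2L, bf_[i, ])
    for (k in seq_len(nd)) diffs[, k] <- diffs[, k] * sp[k]
    sqrt(min(rowSums(diffs^2)))
  }, 0)
}

# Face-neighbour boundary (4-connectivity in 2D), written independently of
# the package's shift-based implementation.
oracle_boundary <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  idx <- which(m, arr.ind = TRUE)
  if (length(idx) == 0L) return(out)
  nd <- length(d)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    on_edge <- FALSE
    for (k in seq_len(nd)) {
      for (s in c(-1L, 1L)) {
        q <- p
        q[k] <- q[k] + s
        if (q[k] < 1L || q[k] > d[k]) {
          on_edge <- TRUE
        } else if (!m[matrix(q, 1L)]) {
          on_edge <- TRUE
        }
      }
    }
    if (on_edge) out[matrix(p, 1L)] <- TRUE
  }
  out
}

# Random blobby binary mask for metric tests.
random_mask <- function(h, w, p = 0.3, smooth = TRUE) {
  m <- matrix(stats::runif(h * w) < p, h, w)
  if (smooth) {
    # one majority-vote smoothing pass keeps blobs but avoids salt noise
    padded <- matrix(FALSE, h + 2L, w + 2L)
    padded[2:(h + 1L), 2:(w + 1L)] <- m
    cnt <- padded[1:h, 2:(w + 1L)] + padded[3:(h + 2L), 2:(w + 1L)] +
      padded[2:(h + 1L), 1:w] + padded[2:(h + 1L), 3:(w + 2L)] + m
    m <- cnt >= 3L
  }
  m
}

rand_nchw <- function(n, c, h, w, sd = 1) {
  array(stats::rnorm(n * c * h * w, sd = sd), c(n, c, h, w))
}

# Internal-namespace accessor used by engine-level tests.
int_ <- function(name) get(name, envir = asNamespace("dganet"))
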