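# Composite training loss: pixel-wise cross-entropy plus soft Dice loss over
# the foreground classes, L = L_CE + L_DC.

check_probs_labels <- function(probs, labels) {
  stopifnot(length(dim(probs)) == 4L)
  K <- dim(probs)[2L]
  if (!all(labels %in% 0:(K - 1L))) {
    stop(sprintf("labels must lie in [0, %d]", K - 1L), call. = FALSE)
  }
  if (!identical(as.integer(dim(probs)[-2L]), as.integer(dim(labels)))) {
    stop("label shape must match (batch, H, W) of the probabilities", call. = FALSE)
  }
  invisible(K)
}

# One-hot label array in (H, W, C, N) layout.
one_hot_hwcn <- function(labels, K) {
  d <- dim(labels) # (N, H, W)
  out <- array(0, c(d[2L], d[3L], K, d[1L]))
  lp <- aperm(labels, c(2L, 3L, 1L)) # (H, W, N)
  for (k in seq_len(K) - 1L) {
    out[, , k + 1L, ] <- as.numeric(lp == k)
  }
  out
}

# Engine-level cross-entropy: probs node (H, W, K, N), onehot array.
op_cross_entropy <- function(probs, onehot, eps = 1e-7) {
  v <- probs$value
  n_pix <- length(v) / dim(v)[3L]
  pc <- pmax(v, eps)
  val <- -sum(onehot * log(pc)) / n_pix
  tn_new(val, list(probs), function(g) {
    # -y / max(p, eps): clamping bounds the gradient but must not zero it,
    # or saturated-wrong pixels would stop learning
    dv <- -(as.numeric(g) / n_pix) * onehot / pmax(v, eps)
    list(dv)
  })
}

# Numerically fused cross-entropy on logits (log-sum-exp form). The gradient
# is the exact (softmax - onehot)/N, which cannot vanish on saturated-wrong
# pixels the way a clamped -y/p can; training uses this path, the public
# probability-based cross_entropy_loss() keeps the documented clamp.
op_cross_entropy_logits <- function(logits, onehot) {
  z <- logits$value
  d <- dim(z)
  K <- d[3L]
  n_pix <- length(z) / K
  perm <- c(3L, 1L, 2L, 4L)
  inv_perm <- order(perm)
  zp <- matrix(aperm(z, perm), K)
  mx <- col_max(zp)
  e <- exp(zp - rep(mx, each = K))
  lse <- log(colSums(e)) + mx
  p <- e / rep(colSums(e), each = K)
  yp <- matrix(aperm(onehot, perm), K)
  val <- -sum(yp * (zp - rep(lse, each = K))) / n_pix
  tn_new(val, list(logits), function(g) {
    dzp <- (p - yp) * (as.numeric(g) / n_pix)
    dim(dzp) <- d[perm]
    list(aperm(dzp, inv_perm))
  })
}

# Engine-level soft Dice loss over foreground classes.
op_soft_dice <- function(probs, onehot, smooth = 1e-5) {
  v <- probs$value
  K <- dim(v)[3L]
  fg <- seq(2L, K)
  num <- den <- dice <- numeric(length(fg))
  for (i in seq_along(fg)) {
    k <- fg[i]
    pk <- v[, , k, , drop = FALSE]
    yk <- onehot[, , k, , drop = FALSE]
    num[i] <- 2 * sum(pk * yk) + smooth
    den[i] <- sum(pk) + sum(yk) + smooth
    dice[i] <- num[i] / den[i]
  }
  val <- 1 - mean(dice)
  tn_new(val, list(probs), function(g) {
    dv <- array(0, dim(v))
    for (i in seq_along(fg)) {
      k <- fg[i]
      yk <- onehot[, , k, , drop = FALSE]
      # d(dice_i)/dp = (2*y*den - num) / den^2
      dv[, , k, ] <- -(2 * yk * den[i] - num[i]) / (den[i]^2 * length(fg))
    }
    list(dv * as.numeric(g))
  })
}

#' Pixel-wise cross-entropy loss
#'
#' `-(1/N) * sum(log p(true class))` over all `N` pixels, with probabilities
#' clamped at `1e-7` before the logarithm.
#'
#' @param probs `(batch, classes, H, W)` array of per-pixel probabilities.
#' @param labels integer `(batch, H, W)` array with values in
#'   `[0, classes)`.
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(probs, labels) {
  labels <- as_label_array(labels, probs)
  K <- check_probs_labels(probs, labels)
  p <- as_hwcn(probs)
  no_grad(op_cross_entropy(tn_const(p), one_hot_hwcn(labels, K)))$value
}

#' Soft Dice loss over foreground classes
#'
#' For each foreground class `c`: `dice_c = (2 sum(p_c y_c) + s) /
#' (sum(p_c) + sum(y_c) + s)` with smoothing `s = 1e-5`; the loss is
#' `1 - mean(dice_c)`. Background is excluded, reflecting the class-imbalance
#' motivation of the Dice term.
#'
#' @inheritParams cross_entropy_loss
#' @return Scalar loss.
#' @export
soft_dice_loss <- function(probs, labels) {
  labels <- as_label_array(labels, probs)
  K <- check_probs_labels(probs, labels)
  p <- as_hwcn(probs)
  no_grad(op_soft_dice(tn_const(p), one_hot_hwcn(labels, K)))$value
}

#' Combined segmentation loss
#'
#' @inheritParams cross_entropy_loss
#' @return `list(total, ce, dice)` with `total = ce + dice` exactly.
#' @export
total_loss <- function(probs, labels) {
  ce <- cross_entropy_loss(probs, labels)
  dc <- soft_dice_loss(probs, labels)
  list(total = ce + dc, ce = ce, dice = dc)
}

as_label_array <- function(labels, probs) {
  if (is.matrix(labels)) {
    labels <- array(labels, c(1L, nrow(labels), ncol(labels)))
  }
  if (length(dim(labels)) != 3L) stop("labels must be a (batch, H, W) array", call. = FALSE)
  labels
}
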