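# Reverse-mode automatic differentiation on plain numeric arrays.
#
# The engine is deliberately small: a tensor node is an environment holding a
# value, an optional gradient, the parent nodes and a closure that maps the
# incoming gradient to per-parent gradients. Node ids increase with creation
# order, and every operation's parents pre-date the node, so decreasing id
# order is a valid reverse topological order for backpropagation.
#
# Feature maps use an (H, W, C, N) column-major layout internally; the
# user-facing API speaks the field's usual (N, C, H, W) convention and
# converts at the boundary (see feature_map()).

.dga <- new.env(parent = emptyenv())
.dga$grad_on <- TRUE
.dga$training <- FALSE
.dga$node_id <- 0L
.dga$mac_count <- NULL # numeric when operation counting is active
.dga$cache <- new.env(parent = emptyenv())

tn_new <- function(value, parents = list(), backfn = NULL) {
  rg <- isTRUE(.dga$grad_on) && length(parents) > 0L &&
    any(vapply(parents, function(p) isTRUE(p$requires_grad), FALSE))
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$requires_grad <- rg
  if (rg) {
    node$parents <- parents
    node$backfn <- backfn
  } else {
    node$parents <- list()
    node$backfn <- NULL
  }
  .dga$node_id <- .dga$node_id + 1L
  node$id <- .dga$node_id
  class(node) <- "dga_tensor"
  node
}

tn_param <- function(value, name = NULL) {
  node <- tn_new(value)
  node$requires_grad <- TRUE
  node$is_param <- TRUE
  node$name <- name
  node
}

tn_const <- function(value) tn_new(value)

is_tensor <- function(x) inherits(x, "dga_tensor")

as_tensor <- function(x) if (is_tensor(x)) x else tn_const(x)

#' @export
print.dga_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat(sprintf(
    "<dga_tensor id=%d dim=[%s]%s%s>\n", x$id,
    paste(if (is.null(d)) length(x$value) else d, collapse = ","),
    if (isTRUE(x$requires_grad)) " grad" else "",
    if (isTRUE(x$is_param)) " param" else ""
  ))
  invisible(x)
}

# Evaluate `expr` with the tape disabled (pure forward computation).
no_grad <- function(expr) {
  old <- .dga$grad_on
  .dga$grad_on <- FALSE
  on.exit(.dga$grad_on <- old)
  expr
}

with_training_mode <- function(on, expr) {
  old <- .dga$training
  .dga$training <- on
  on.exit(.dga$training <- old)
  expr
}

# Backpropagate from `root` (typically a scalar loss). Gradients accumulate
# on every reachable node flagged is_param; intermediate gradients are
# released as soon as they have been consumed.
tn_backward <- function(root, seed = NULL) {
  if (is.null(seed)) {
    seed <- root$value
    seed[] <- 1
  }
  nodes <- new.env(parent = emptyenv())
  work <- list(root)
  nw <- 1L
  while (nw > 0L) {
    n <- work[[nw]]
    work[[nw]] <- NULL
    nw <- nw - 1L
    key <- as.character(n$id)
    if (!is.null(nodes[[key]])) next
    nodes[[key]] <- n
    for (p in n$parents) {
      if (isTRUE(p$requires_grad)) {
        nw <- nw + 1L
        work[[nw]] <- p
      }
    }
  }
  ids <- sort(as.integer(ls(nodes)), decreasing = TRUE)
  root$grad <- seed
  for (id in ids) {
    n <- nodes[[as.character(id)]]
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad)
    ps <- n$parents
    for (i in seq_along(ps)) {
      p <- ps[[i]]
      g <- gs[[i]]
      if (!isTRUE(p$requires_grad) || is.null(g)) next
      if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
    }
    if (!isTRUE(n$is_param)) n$grad <- NULL
  }
  invisible(root)
}

count_mul <- function(n) {
  if (!is.null(.dga$mac_count)) .dga$mac_count <- .dga$mac_count + n
  invisible(NULL)
}

# Run `expr` while counting multiply operations in conv / matmul /
# element-wise product ops; returns the count.
with_mul_counter <- function(expr) {
  old <- .dga$mac_count
  .dga$mac_count <- 0
  on.exit(.dga$mac_count <- old)
  force(expr)
  .dga$mac_count
}
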