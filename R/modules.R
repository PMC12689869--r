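# Minimal module system: a module is a list with named parameter nodes,
# child modules, optional mutable state (an environment, e.g. batch-norm
# running statistics) and a forward closure called as m$forward(m, ...).

new_module <- function(type, forward, params = list(), children = list(),
                       state = NULL) {
  m <- list(type = type, forward = forward, params = params,
            children = children, state = state)
  class(m) <- "dga_module"
  m
}

#' @export
print.dga_module <- function(x, ...) {
  cat(sprintf("<dga_module %s: %s parameters>\n", x$type,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

m_fwd <- function(m, ...) m$forward(m, ...)

# Flat named list of all parameter nodes in a module tree.
module_parameters <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params)) {
    out[[paste0(prefix, nm)]] <- m$params[[nm]]
  }
  for (nm in names(m$children)) {
    out <- c(out, module_parameters(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

n_parameters <- function(m) {
  sum(vapply(module_parameters(m), function(p) length(p$value), 0))
}

zero_grads <- function(m) {
  for (p in module_parameters(m)) p$grad <- NULL
  invisible(m)
}

# Overwrite every parameter value (mainly for the residual-identity tests).
fill_parameters <- function(m, value = 0) {
  for (p in module_parameters(m)) p$value[] <- value
  invisible(m)
}

# Assign a single named parameter (names as reported by module_parameters).
set_parameter <- function(m, name, value) {
  ps <- module_parameters(m)
  if (is.null(ps[[name]])) {
    stop(sprintf("unknown parameter '%s'; available: %s", name,
                 paste(names(ps), collapse = ", ")), call. = FALSE)
  }
  stopifnot(length(value) == 1L || length(value) == length(ps[[name]]$value))
  ps[[name]]$value[] <- value
  invisible(m)
}

rnorm_array <- function(d, sd) array(stats::rnorm(prod(d), sd = sd), d)

# ---- basic layers -----------------------------------------------------------

# He-initialised stride-1 convolution; padding preserves spatial size.
layer_conv2d <- function(cin, cout, k = 3L, dil = 1L, bias = TRUE) {
  fan_in <- k * k * cin
  w <- tn_param(rnorm_array(c(k, k, cin, cout), sd = sqrt(2 / fan_in)))
  params <- list(weight = w)
  if (bias) params$bias <- tn_param(rep(0, cout))
  new_module("conv2d", params = params, forward = function(m, x) {
    op_conv2d(x, m$params$weight, m$params$bias, dil = dil)
  })
}

layer_batchnorm <- function(c) {
  state <- new.env(parent = emptyenv())
  state$running_mean <- rep(0, c)
  state$running_var <- rep(1, c)
  new_module("batchnorm",
    params = list(gamma = tn_param(rep(1, c)), beta = tn_param(rep(0, c))),
    state = state,
    forward = function(m, x) op_batchnorm(x, m$params$gamma, m$params$beta, m$state)
  )
}

layer_layernorm <- function(c) {
  new_module("layernorm",
    params = list(gamma = tn_param(rep(1, c)), beta = tn_param(rep(0, c))),
    forward = function(m, x) op_layernorm_c(x, m$params$gamma, m$params$beta)
  )
}

# Sequential composition.
layer_seq <- function(...) {
  children <- list(...)
  names(children) <- sprintf("s%d", seq_along(children))
  new_module("seq", children = children, forward = function(m, x) {
    for (ch in m$children) x <- m_fwd(ch, x)
    x
  })
}
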