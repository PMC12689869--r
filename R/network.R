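# Assembly of the full DGA-Net: two five-stage encoder branches (FSMF and
# MAHA) and a five-stage GMCA decoder, plus the classification head and
# parameter / multiply-accumulate accounting.
#
# Stage resolutions (relative to the input): 1, 1/2, 1/4, 1/8, 1/16 for both
# branches. Stage 1 of each branch keeps full resolution (the FSMF stem is
# conFFT + conOp; the MAHA stem is a pool-free double convolution), stages
# 2-4 are DConv blocks whose trailing max-pool advances the resolution level,
# and stage 5 applies a max-pool followed by the branch's specialty units
# (two stacked FSMF units / one MAHA unit; the MAHA branch also has a MAHA
# unit at stage 4).

#' Network configuration
#'
#' All architecture hyperparameters of DGA-Net. The default stage widths
#' (20, 40, 80, 172, 336) were calibrated once so that the full network at
#' its reference 512x512 single-channel input carries 13.91 million trainable
#' parameters (13.90M, within 0.1%), and then frozen.
#'
#' @param in_channels input channels (CT slices are single-channel).
#' @param num_classes segmentation classes (background, liver, tumor).
#' @param stage_widths five non-decreasing integers, each divisible by 4.
#' @param miaf_heads head count of the decoder cross-attention.
#' @param token_budget maximum token count in the decoder cross-attention;
#'   larger grids are average-pooled before attending.
#' @param input_size reference `(H, W)` used to size the attention positional
#'   tables (rescaled automatically at other run-time sizes).
#' @param seed integer seed for deterministic parameter initialisation.
#' @param disable_fsmf,disable_confft,disable_gmca,disable_maha,single_branch,concat_combine
#'   ablation switches mirroring the module-removal experiments: replace the
#'   FSMF units, the conFFT stem, the GMCA stages or the MAHA units with
#'   plain convolutions, drop the FSMF branch entirely, or combine the MIAF
#'   arms by concatenation instead of addition.
#' @return A validated list of class `dganet_config`.
#' @export
dganet_config <- function(in_channels = 1L,
                          num_classes = 3L,
                          stage_widths = c(20L, 40L, 80L, 172L, 336L),
                          miaf_heads = 4L,
                          token_budget = 4096L,
                          input_size = c(512L, 512L),
                          seed = 42L,
                          disable_fsmf = FALSE,
                          disable_confft = FALSE,
                          disable_gmca = FALSE,
                          disable_maha = FALSE,
                          single_branch = FALSE,
                          concat_combine = FALSE) {
  cfg <- list(
    in_channels = as.integer(in_channels),
    num_classes = as.integer(num_classes),
    stage_widths = as.integer(stage_widths),
    miaf_heads = as.integer(miaf_heads),
    token_budget = as.integer(token_budget),
    input_size = as.integer(rep(input_size, length.out = 2L)),
    seed = as.integer(seed),
    disable_fsmf = isTRUE(disable_fsmf),
    disable_confft = isTRUE(disable_confft),
    disable_gmca = isTRUE(disable_gmca),
    disable_maha = isTRUE(disable_maha),
    single_branch = isTRUE(single_branch),
    concat_combine = isTRUE(concat_combine)
  )
  class(cfg) <- "dganet_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  w <- cfg$stage_widths
  if (length(w) != 5L) stop("stage_widths must have 5 entries", call. = FALSE)
  if (any(w %% 4L != 0L)) {
    stop("every stage width must be divisible by 4 (channel grouping)", call. = FALSE)
  }
  if (any(diff(w) < 0L)) stop("stage widths must be non-decreasing", call. = FALSE)
  if (cfg$num_classes < 2L) stop("num_classes must be at least 2", call. = FALSE)
  if (any(cfg$input_size %% 16L != 0L)) {
    stop("reference input size must be divisible by 16 (four resolution halvings)",
         call. = FALSE)
  }
  if (cfg$miaf_heads < 1L || cfg$stage_widths[1L] %% cfg$miaf_heads != 0L) {
    stop("stage widths must be divisible by the MIAF head count", call. = FALSE)
  }
  invisible(cfg)
}

#' Desk-scale configuration
#'
#' A width-8 variant for CPU experiments on 96x96 phantom slices: same
#' topology, minimal widths, and a 256-token attention budget so the decoder
#' cross-attention stays tractable without a GPU.
#'
#' @param ... overrides forwarded to [dganet_config()].
#' @export
dganet_desk_config <- function(...) {
  args <- utils::modifyList(
    list(stage_widths = c(8L, 8L, 8L, 8L, 8L), token_budget = 256L,
         input_size = c(96L, 96L)),
    list(...)
  )
  do.call(dganet_config, args)
}

local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  code
}

#' Build the full DGA-Net
#'
#' Wires the FSMF and MAHA encoder branches and the five GMCA decoder stages
#' per the configuration; parameter initialisation is deterministic in
#' `cfg$seed`.
#'
#' @param cfg a [dganet_config()].
#' @return A module tree of class `dganet` (also `dga_module`).
#' @export
build_dganet <- function(cfg) {
  validate_config(cfg)
  w <- cfg$stage_widths
  h0 <- cfg$input_size[1L]
  w0 <- cfg$input_size[2L]
  local_seed(cfg$seed, {
    ch <- list()
    if (!cfg$single_branch) {
      if (cfg$disable_confft) {
        ch$f_stem <- make_con_op(cfg$in_channels, w[1L])
      } else {
        ch$f_stem_fft <- make_conv_fft(cfg$in_channels, w[1L])
        ch$f_stem <- make_con_op(w[1L], w[1L])
      }
      ch$f2 <- make_dconv(w[1L], w[2L])
      ch$f3 <- make_dconv(w[2L], w[3L])
      ch$f4 <- make_dconv(w[3L], w[4L])
      ch$f5_proj <- layer_conv2d(w[4L], w[5L], k = 1L)
      if (cfg$disable_fsmf) {
        ch$f5a <- make_double_conv(w[5L], w[5L])
        ch$f5b <- make_double_conv(w[5L], w[5L])
      } else {
        ch$f5a <- make_fsmf(w[5L])
        ch$f5b <- make_fsmf(w[5L])
      }
    }
    ch$m1 <- make_double_conv(cfg$in_channels, w[1L])
    ch$m2 <- make_dconv(w[1L], w[2L])
    ch$m3 <- make_dconv(w[2L], w[3L])
    if (cfg$disable_maha) {
      ch$m4 <- make_double_conv(w[3L], w[4L])
      ch$m5 <- make_double_conv(w[4L], w[5L])
    } else {
      ch$m4 <- make_maha(w[3L], w[4L], h0 %/% 8L, w0 %/% 8L)
      ch$m5 <- make_maha(w[4L], w[5L], h0 %/% 16L, w0 %/% 16L)
    }
    c_bottom <- if (cfg$single_branch) w[5L] else 2L * w[5L]
    ch$fuse0 <- layer_conv2d(c_bottom, w[5L], k = 1L)
    combine <- if (cfg$concat_combine) "concat" else "add"
    mk_stage <- function(c_prev, c_skip, width, upsample) {
      if (cfg$disable_gmca) {
        n_in <- if (cfg$single_branch) 2L else 3L
        make_plain_decoder(c_prev + (n_in - 1L) * c_skip, width, upsample)
      } else {
        make_gmca(c_prev, c_skip, width, heads = cfg$miaf_heads,
                  token_budget = cfg$token_budget, combine = combine,
                  upsample = upsample, single_branch = cfg$single_branch)
      }
    }
    ch$d1 <- mk_stage(w[5L], w[5L], w[5L], upsample = FALSE)
    ch$d2 <- mk_stage(w[5L], w[4L], w[4L], upsample = TRUE)
    ch$d3 <- mk_stage(w[4L], w[3L], w[3L], upsample = TRUE)
    ch$d4 <- mk_stage(w[3L], w[2L], w[2L], upsample = TRUE)
    ch$d5 <- mk_stage(w[2L], w[1L], w[1L], upsample = TRUE)
    ch$head <- layer_conv2d(w[1L], cfg$num_classes, k = 1L)
    net <- new_module("dganet", children = ch, forward = dganet_forward_impl)
    net$config <- cfg
    class(net) <- c("dganet", "dga_module")
    net
  })
}

# Decoder stand-in when GMCA is ablated: concat + double convolution.
make_plain_decoder <- function(c_in, width, upsample) {
  conv <- make_double_conv(c_in, width)
  new_module("plain_decoder", children = list(conv = conv),
             forward = function(m, prev, fl, mh) {
    up <- if (upsample) op_upsample2(prev) else prev
    ins <- list(up, fl, mh)
    ins <- ins[!vapply(ins, is.null, FALSE)]
    m_fwd(m$children$conv, op_concat_c(ins))
  })
}

# Engine-level forward pass: x is an (H, W, C, N) tensor node; returns
# per-pixel class probabilities (softmax over the channel axis).
dganet_forward_impl <- function(m, x) {
  op_softmax_dims(dganet_logits_impl(m, x), 3L)
}

# Forward pass up to the classification head (pre-softmax logits); training
# pairs these with the fused log-sum-exp cross-entropy.
dganet_logits_impl <- function(m, x) {
  cfg <- m$config
  ch <- m$children
  d <- dim(x$value)
  need <- if (!cfg$single_branch && !cfg$disable_fsmf) 32L else 16L
  if (d[1L] %% need != 0L || d[2L] %% need != 0L) {
    stop(sprintf(
      "input spatial size must be divisible by %d (four halvings%s); pad first (see predict_volume)",
      need,
      if (need == 32L) " plus the FSMF down/up pass at the deepest stage" else ""
    ), call. = FALSE)
  }
  # MAHA branch
  m1 <- m_fwd(ch$m1, x)
  m2 <- m_fwd(ch$m2, m1)
  m3 <- m_fwd(ch$m3, m2)
  m4 <- m_fwd(ch$m4, op_maxpool2(m3))
  m5 <- m_fwd(ch$m5, op_maxpool2(m4))
  if (cfg$single_branch) {
    s1 <- s2 <- s3 <- s4 <- s5 <- NULL
    bottom <- m_fwd(ch$fuse0, m5)
  } else {
    s1 <- if (cfg$disable_confft) {
      m_fwd(ch$f_stem, x)
    } else {
      m_fwd(ch$f_stem, m_fwd(ch$f_stem_fft, x))
    }
    s2 <- m_fwd(ch$f2, s1)
    s3 <- m_fwd(ch$f3, s2)
    s4 <- m_fwd(ch$f4, s3)
    s5 <- m_fwd(ch$f5b, m_fwd(ch$f5a, m_fwd(ch$f5_proj, op_maxpool2(s4))))
    bottom <- m_fwd(ch$fuse0, op_concat_c(list(s5, m5)))
  }
  dck <- m_fwd(ch$d1, bottom, s5, m5)
  dck <- m_fwd(ch$d2, dck, s4, m4)
  dck <- m_fwd(ch$d3, dck, s3, m3)
  dck <- m_fwd(ch$d4, dck, s2, m2)
  dck <- m_fwd(ch$d5, dck, s1, m1)
  m_fwd(ch$head, dck)
}

#' Forward pass on a batch of slices
#'
#' @param net a built [build_dganet()] network.
#' @param x `(N, C, H, W)` array of normalized slices, `H`/`W` divisible by 16.
#' @param training run in training mode (batch statistics)? Default FALSE.
#' @return `(N, num_classes, H, W)` array of per-pixel class probabilities.
#' @export
dganet_forward <- function(net, x, training = FALSE) {
  v <- as_hwcn(fm_data(x))
  out <- no_grad(with_training_mode(training, m_fwd(net, tn_const(v))))
  as_nchw(out$value)
}

#' Count trainable parameters
#'
#' @param net a built network (or any module).
#' @return Total number of trainable scalar parameters.
#' @export
count_parameters <- function(net) n_parameters(net)

#' Count multiply-accumulate operations of one forward pass
#'
#' Counts the multiplications performed by convolutions, attention matrix
#' products and element-wise feature products during a single-slice forward
#' pass at the given input size. Reported FLOPs are `2 x MACs` by definition.
#'
#' @param net a built network or block module.
#' @param input_size `(H, W)` spatial size.
#' @param in_channels input channels (defaults to the network config).
#' @return Number of MACs (numeric).
#' @export
count_macs <- function(net, input_size, in_channels = NULL) {
  if (is.null(in_channels)) {
    in_channels <- if (!is.null(net$config)) net$config$in_channels else 1L
  }
  x <- tn_const(array(0, c(input_size[1L], input_size[2L], in_channels, 1L)))
  with_mul_counter(no_grad(with_training_mode(FALSE, m_fwd(net, x))))
}

#' @rdname count_macs
#' @export
count_flops <- function(net, input_size, in_channels = NULL) {
  2 * count_macs(net, input_size, in_channels)
}

# ---- checkpoints -------------------------------------------------------------

module_states <- function(m, prefix = "") {
  out <- list()
  if (!is.null(m$state)) out[[prefix]] <- as.list(m$state)
  for (nm in names(m$children)) {
    out <- c(out, module_states(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

restore_states <- function(m, states, prefix = "") {
  if (!is.null(m$state)) {
    st <- states[[prefix]]
    for (nm in names(st)) m$state[[nm]] <- st[[nm]]
  }
  for (nm in names(m$children)) {
    restore_states(m$children[[nm]], states, paste0(prefix, nm, "."))
  }
  invisible(m)
}

config_checksum <- function(json) {
  b <- utf8ToInt(json)
  sum(b * (seq_along(b) %% 997L)) %% 2147483647L
}

#' Save / load a network checkpoint
#'
#' The checkpoint stores the configuration as JSON text, all named parameter
#' arrays, the batch-normalization running statistics and a checksum of the
#' configuration; the loader rebuilds the network and validates the checksum.
#'
#' @param net a built network.
#' @param path file path (`.dgk`).
#' @param extra optional named list stored verbatim (e.g. training history).
#' @export
save_checkpoint <- function(net, path, extra = list()) {
  cfg_json <- jsonlite::toJSON(unclass(net$config), auto_unbox = TRUE, digits = NA)
  params <- lapply(module_parameters(net), function(p) p$value)
  obj <- list(
    format = "dganet-checkpoint-1",
    config_json = as.character(cfg_json),
    checksum = config_checksum(as.character(cfg_json)),
    params = params,
    states = module_states(net),
    extra = extra
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns `list(net, config, extra)`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "dganet-checkpoint-1")) {
    stop("not a dganet checkpoint", call. = FALSE)
  }
  if (config_checksum(obj$config_json) != obj$checksum) {
    stop("checkpoint config checksum mismatch", call. = FALSE)
  }
  raw <- jsonlite::fromJSON(obj$config_json)
  cfg <- do.call(dganet_config, raw)
  net <- build_dganet(cfg)
  ps <- module_parameters(net)
  if (!setequal(names(ps), names(obj$params))) {
    stop("checkpoint parameters do not match the rebuilt architecture", call. = FALSE)
  }
  for (nm in names(ps)) ps[[nm]]$value[] <- obj$params[[nm]]
  restore_states(net, obj$states)
  list(net = net, config = cfg, extra = obj$extra)
}
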