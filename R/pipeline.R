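# Training / prediction / evaluation pipeline: nnU-Net-style preprocessing,
# SGD with polynomial learning-rate decay, slicewise prediction with
# reflective padding, and metric reporting.

#' Training configuration
#'
#' Defaults follow the published recipe: batch size 4, SGD (momentum 0.99,
#' Nesterov) at initial learning rate 0.01 with polynomial decay
#' `lr0 * (1 - epoch/epoch_max)^0.9`, loss = cross-entropy + Dice, foreground
#' quantile clip 0.5-99.5%, HU window [-17, 201], z-normalization constants
#' 99.04 / 39.36, target in-plane spacing 0.7676 mm, seed 42. `max_epochs`
#' defaults to the published 1000; desk-scale runs pass 10-15 epochs or cap
#' `max_steps`.
#'
#' @param batch_size slices per optimization step.
#' @param max_epochs maximum training epochs.
#' @param max_steps optional cap on total optimization steps.
#' @param lr0 initial learning rate.
#' @param poly_exponent polynomial decay exponent.
#' @param momentum SGD momentum (Nesterov).
#' @param clip_norm global gradient-norm clip (the reference training
#'   framework's default of 12); `Inf` disables clipping.
#' @param clip_quantiles foreground quantile clipping range.
#' @param hu_window intensity window in HU.
#' @param norm_mean,norm_sd z-normalization constants.
#' @param target_spacing target in-plane spacing in mm.
#' @param foreground_hu lower HU bound defining "foreground" voxels for the
#'   quantile clip.
#' @param seed training seed (data order and initialisation).
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 4L, max_epochs = 1000L, max_steps = NULL,
                         lr0 = 0.01, poly_exponent = 0.9, momentum = 0.99,
                         clip_norm = 12,
                         clip_quantiles = c(0.005, 0.995),
                         hu_window = c(-17, 201),
                         norm_mean = 99.04, norm_sd = 39.36,
                         target_spacing = 0.7676, foreground_hu = -200,
                         seed = 42L) {
  cfg <- list(batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
              lr0 = lr0, poly_exponent = poly_exponent, momentum = momentum,
              clip_norm = clip_norm,
              clip_quantiles = clip_quantiles, hu_window = hu_window,
              norm_mean = norm_mean, norm_sd = norm_sd,
              target_spacing = target_spacing, foreground_hu = foreground_hu,
              seed = as.integer(seed))
  class(cfg) <- "train_config"
  cfg
}

#' Polynomial learning-rate schedule
#'
#' `lr(e) = lr0 * (1 - e/e_max)^p`, non-increasing and 0 from `e_max` on.
#'
#' @param epoch 0-based epoch index.
#' @param cfg a [train_config()].
#' @return Learning rate.
#' @export
lr_schedule <- function(epoch, cfg) {
  if (epoch >= cfg$max_epochs) return(0)
  cfg$lr0 * (1 - epoch / cfg$max_epochs)^cfg$poly_exponent
}

#' Preprocess a HU volume
#'
#' (1) clip to the 0.5-99.5% quantiles of the foreground voxels (HU above
#' `cfg$foreground_hu`; falls back to whole-volume quantiles with a warning
#' if no voxel qualifies); (2) clamp to the `[-17, 201]` HU window;
#' (3) z-normalize with the configured constants.
#'
#' @param hu_volume numeric array of Hounsfield intensities.
#' @param cfg a [train_config()].
#' @return Normalized array of the input shape.
#' @export
preprocess_volume <- function(hu_volume, cfg = train_config()) {
  stopifnot_finite(hu_volume, "HU volume")
  fg <- hu_volume > cfg$foreground_hu
  if (!any(fg)) {
    warning("no foreground voxels above the HU threshold; using whole-volume quantiles")
    fg <- rep(TRUE, length(hu_volume))
  }
  q <- stats::quantile(hu_volume[fg], cfg$clip_quantiles, names = FALSE, type = 7)
  x <- pmin(pmax(hu_volume, q[1L]), q[2L])
  x <- pmin(pmax(x, cfg$hu_window[1L]), cfg$hu_window[2L])
  (x - cfg$norm_mean) / cfg$norm_sd
}

#' Deterministic 7:1:2 split
#'
#' @param n case count (or a list of cases, for convenience).
#' @param ratio three nonnegative weights (train, val, test).
#' @param seed shuffle seed.
#' @return `list(train, val, test)` of disjoint, exhaustive index vectors.
#' @export
split_cases <- function(n, ratio = c(7, 1, 2), seed = 42L) {
  if (is.list(n)) n <- length(n)
  stopifnot(n >= 1L, length(ratio) == 3L, all(ratio >= 0))
  idx <- local_seed(seed, sample.int(n))
  p <- ratio / sum(ratio)
  n_val <- floor(n * p[2L])
  n_test <- floor(n * p[3L])
  n_train <- n - n_val - n_test
  list(train = sort(idx[seq_len(n_train)]),
       val = sort(idx[n_train + seq_len(n_val)]),
       test = sort(idx[n_train + n_val + seq_len(n_test)]))
}

# Flatten cases into per-slice training examples (normalized image, labels).
cases_to_slices <- function(cases, cfg) {
  xs <- list()
  ys <- list()
  for (cs in cases) {
    norm <- preprocess_volume(cs$hu_volume, cfg)
    for (s in seq_len(dim(norm)[1L])) {
      xs[[length(xs) + 1L]] <- norm[s, , ]
      ys[[length(ys) + 1L]] <- cs$label_volume[s, , ]
    }
  }
  list(x = xs, y = ys)
}

sgd_step <- function(params, velocity, lr, momentum, clip_norm = Inf) {
  if (is.finite(clip_norm)) {
    sq <- 0
    for (p in params) if (!is.null(p$grad)) sq <- sq + sum(p$grad^2)
    gn <- sqrt(sq)
    if (gn > clip_norm) {
      sc <- clip_norm / gn
      for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * sc
    }
  }
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    v <- momentum * velocity[[nm]] + g
    velocity[[nm]] <- v
    p$value <- p$value - lr * (g + momentum * v) # Nesterov update
  }
  velocity
}

#' Train DGA-Net on labeled cases
#'
#' Deterministic under the configured seeds (initialisation, data order; no
#' augmentation). Logs the mean training loss per epoch and, when validation
#' cases are supplied, retains the parameters of the epoch with the best
#' validation mean foreground DPC.
#'
#' @param train_cases list of cases (each with `hu_volume` (S, H, W) and
#'   `label_volume`), e.g. [generate_case()] phantoms.
#' @param net_config a [dganet_config()].
#' @param cfg a [train_config()].
#' @param val_cases optional validation cases for checkpoint selection.
#' @param checkpoint_path optional path; the selected network is saved there.
#' @param verbose print per-epoch loss.
#' @return `list(net, history, best_epoch, best_val_dpc)`.
#' @export
train_dganet <- function(train_cases, net_config, cfg = train_config(),
                         val_cases = NULL, checkpoint_path = NULL,
                         verbose = FALSE) {
  stopifnot(length(train_cases) >= 1L)
  net <- build_dganet(net_config)
  data <- cases_to_slices(train_cases, cfg)
  n_slices <- length(data$x)
  params <- module_parameters(net)
  velocity <- lapply(params, function(p) {
    v <- p$value
    v[] <- 0
    v
  })
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        loss = numeric(0), ce = numeric(0), dice = numeric(0),
                        val_dpc = numeric(0))
  best <- list(epoch = NA_integer_, dpc = -Inf, params = NULL)
  step <- 0L
  done <- FALSE
  local_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs) - 1L) {
      lr <- lr_schedule(epoch, cfg)
      order_idx <- sample.int(n_slices)
      ep_loss <- ep_ce <- ep_dc <- 0
      n_batches <- 0L
      for (b0 in seq(1L, n_slices, by = cfg$batch_size)) {
        idx <- order_idx[b0:min(b0 + cfg$batch_size - 1L, n_slices)]
        hw <- dim(data$x[[1L]])
        xb <- array(0, c(hw[1L], hw[2L], 1L, length(idx)))
        oh <- array(0, c(hw[1L], hw[2L], net_config$num_classes, length(idx)))
        for (j in seq_along(idx)) {
          xb[, , 1L, j] <- data$x[[idx[j]]]
          for (k in seq_len(net_config$num_classes) - 1L) {
            oh[, , k + 1L, j] <- as.numeric(data$y[[idx[j]]] == k)
          }
        }
        loss <- with_training_mode(TRUE, {
          z <- dganet_logits_impl(net, tn_new(xb))
          probs <- op_softmax_dims(z, 3L)
          ce <- op_cross_entropy_logits(z, oh)
          dc <- op_soft_dice(probs, oh)
          op_add(ce, dc)
        })
        if (!is.finite(loss$value)) {
          stop(sprintf("training diverged at epoch %d step %d (loss=%g, ce=%g, dice=%g)",
                       epoch, step, loss$value, ce$value, dc$value), call. = FALSE)
        }
        zero_grads(net)
        tn_backward(loss)
        velocity <- sgd_step(params, velocity, lr, cfg$momentum, cfg$clip_norm)
        ep_loss <- ep_loss + loss$value
        ep_ce <- ep_ce + ce$value
        ep_dc <- ep_dc + dc$value
        n_batches <- n_batches + 1L
        step <- step + 1L
        if (!is.null(cfg$max_steps) && step >= cfg$max_steps) {
          done <- TRUE
          break
        }
      }
      val_dpc <- NA_real_
      if (!is.null(val_cases)) {
        val_dpc <- mean_foreground_dpc(net, val_cases, cfg)
        if (val_dpc > best$dpc) {
          best <- list(epoch = epoch, dpc = val_dpc,
                       params = lapply(params, function(p) p$value))
        }
      }
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr, loss = ep_loss / n_batches,
        ce = ep_ce / n_batches, dice = ep_dc / n_batches, val_dpc = val_dpc
      ))
      if (verbose) {
        message(sprintf("epoch %3d  lr %.5f  loss %.4f  (ce %.4f, dice %.4f)%s",
                        epoch, lr, ep_loss / n_batches, ep_ce / n_batches,
                        ep_dc / n_batches,
                        if (is.na(val_dpc)) "" else sprintf("  val DPC %.4f", val_dpc)))
      }
      if (done) break
    }
  })
  if (!is.null(best$params)) {
    for (nm in names(params)) params[[nm]]$value[] <- best$params[[nm]]
  }
  if (!is.null(checkpoint_path)) {
    save_checkpoint(net, checkpoint_path,
                    extra = list(history = history, best_epoch = best$epoch))
  }
  list(net = net, history = history, best_epoch = best$epoch,
       best_val_dpc = if (is.finite(best$dpc)) best$dpc else NA_real_)
}

# Mean of liver and tumor per-case Dice over a case list (validation metric).
mean_foreground_dpc <- function(net, cases, cfg) {
  ds <- c()
  for (cs in cases) {
    pred <- predict_volume(net, cs$hu_volume, cfg)
    for (cl in c("liver", "tumor")) {
      ds <- c(ds, dice(extract_class_masks(cs$label_volume, cl),
                       extract_class_masks(pred, cl)))
    }
  }
  mean(ds)
}

reflect_index <- function(n, target) {
  # 1, 2, ..., n, n-1, ..., 2, 1, 2, ...: reflection without edge repeats
  base <- if (n > 2L) c(seq_len(n), (n - 1L):2L) else seq_len(n)
  base[((seq_len(target) - 1L) %% length(base)) + 1L]
}

#' Slicewise volume prediction
#'
#' Preprocesses the volume, pads each slice reflectively to a multiple of 16
#' when needed, runs the network in evaluation mode, takes the per-pixel
#' argmax and restacks the slices.
#'
#' @param net a built (trained) network, or a checkpoint path.
#' @param hu_volume `(S, H, W)` array of raw HU intensities.
#' @param cfg a [train_config()] supplying the preprocessing constants.
#' @param batch_slices slices per forward pass.
#' @return Integer `(S, H, W)` label volume with values in `{0, 1, 2}`.
#' @export
predict_volume <- function(net, hu_volume, cfg = train_config(), batch_slices = 8L) {
  if (is.character(net)) net <- load_checkpoint(net)$net
  norm <- preprocess_volume(hu_volume, cfg)
  d <- dim(norm)
  S <- d[1L]; H <- d[2L]; W <- d[3L]
  Hp <- 32L * ceiling(H / 32L)
  Wp <- 32L * ceiling(W / 32L)
  ri <- reflect_index(H, Hp)
  ci <- reflect_index(W, Wp)
  out <- array(0L, d)
  for (b0 in seq(1L, S, by = batch_slices)) {
    idx <- b0:min(b0 + batch_slices - 1L, S)
    xb <- array(0, c(Hp, Wp, 1L, length(idx)))
    for (j in seq_along(idx)) {
      xb[, , 1L, j] <- norm[idx[j], , ][ri, ci]
    }
    probs <- no_grad(with_training_mode(FALSE, m_fwd(net, tn_new(xb))))$value
    for (j in seq_along(idx)) {
      p <- probs[seq_len(H), seq_len(W), , j] # crop the padding back off
      out[idx[j], , ] <- max.col(matrix(p, H * W, dim(probs)[3L]), "first") - 1L
    }
  }
  out
}

#' Evaluate a network on labeled cases
#'
#' @param net built network or checkpoint path.
#' @param cases list of labeled cases.
#' @param cfg a [train_config()].
#' @param case_ids optional identifiers.
#' @return A [metric_report()] (attribute `predictions` holds the label
#'   volumes).
#' @export
evaluate_model <- function(net, cases, cfg = train_config(), case_ids = NULL) {
  if (is.character(net)) net <- load_checkpoint(net)$net
  preds <- lapply(cases, function(cs) predict_volume(net, cs$hu_volume, cfg))
  truths <- lapply(cases, function(cs) cs$label_volume)
  spacing <- if (!is.null(cases[[1L]]$spacing)) cases[[1L]]$spacing else 1
  rep <- metric_report(truths, preds, spacing = spacing, case_ids = case_ids)
  attr(rep, "predictions") <- preds
  rep
}

#' Size-stratified tumor DPC table
#'
#' @param net built network or checkpoint path.
#' @param cases labeled cases with per-tumor diameter records.
#' @param cfg a [train_config()].
#' @return Data frame: stratum, case count, tumor DPC.
#' @export
evaluate_stratified <- function(net, cases, cfg = train_config()) {
  if (is.character(net)) net <- load_checkpoint(net)$net
  strata <- stratify_cases(cases)
  rows <- lapply(names(strata), function(s) {
    ids <- strata[[s]]
    if (length(ids) == 0L) {
      return(data.frame(stratum = s, n_cases = 0L, tumor_dpc = NA_real_))
    }
    pairs <- lapply(cases[ids], function(cs) {
      pred <- predict_volume(net, cs$hu_volume, cfg)
      list(a = extract_class_masks(cs$label_volume, "tumor"),
           b = extract_class_masks(pred, "tumor"))
    })
    data.frame(stratum = s, n_cases = length(ids), tumor_dpc = dpc(pairs))
  })
  do.call(rbind, rows)
}

#' Gaussian-noise robustness protocol
#'
#' Evaluates the same network on clean cases and on copies corrupted with
#' additive Gaussian HU noise, mirroring the noise-perturbation experiment.
#'
#' @param net built network or checkpoint path.
#' @param cases labeled phantom cases.
#' @param noise_sd noise levels (HU) to sweep.
#' @param cfg a [train_config()].
#' @return Data frame: noise sd, liver/tumor DPC and DG.
#' @export
noise_robustness <- function(net, cases, noise_sd = c(0, 10), cfg = train_config()) {
  if (is.character(net)) net <- load_checkpoint(net)$net
  rows <- lapply(noise_sd, function(sdv) {
    noisy <- lapply(cases, function(cs) add_gaussian_noise(cs, sdv))
    rep <- evaluate_model(net, noisy, cfg)
    ag <- rep$aggregate
    data.frame(noise_sd = sdv,
               liver_dpc = ag$dpc[ag$class == "liver"],
               tumor_dpc = ag$dpc[ag$class == "tumor"],
               liver_dg = ag$dg[ag$class == "liver"],
               tumor_dg = ag$dg[ag$class == "tumor"])
  })
  do.call(rbind, rows)
}

#' Generate a phantom dataset
#'
#' @param n_cases number of cases.
#' @param base_spec a [phantom_spec()]; per-case seeds are derived from its
#'   seed.
#' @return List of `phantom_case` objects.
#' @export
generate_dataset <- function(n_cases, base_spec = phantom_spec()) {
  lapply(seq_len(n_cases), function(i) {
    spec <- base_spec
    spec$seed <- (base_spec$seed + 131L * i) %% .Machine$integer.max
    generate_case(spec)
  })
}
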