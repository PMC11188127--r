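## Two-stage training: backbone pretraining on pooled data, then few-pair
## fine-tuning at a reduced learning rate with all layers trainable.
## The optimizer is Adam with global gradient-norm clipping; one master
## seed derives per-epoch/per-batch sub-seeds so runs are reproducible and
## adding epochs never shifts earlier batches.

#' Training configuration
#'
#' @param epochs training epochs (fine-tuning default follows the
#'   30-epoch few-pair protocol).
#' @param steps_per_epoch optimizer steps per epoch.
#' @param batch_size patches per step.
#' @param patch_shape `(F_p, H_p, W_p)` sampled patch size; the frame
#'   extent is clipped to the available frames.
#' @param learning_rate Adam learning rate for backbone / scratch runs.
#' @param lr_finetune reduced learning rate used by [finetune].
#' @param loss_weights named vector `c(mse =, ssim =)`, both `>= 0`, not
#'   both zero.
#' @param seed master seed for init, batch sampling and patch positions.
#' @param grad_clip global gradient-norm clip (`Inf` disables).
#' @param ssim_window SSIM window used inside the loss.
#' @param val_tiling [tiling_spec] for per-epoch full-stack validation
#'   inference (`NULL`: one tile covering the stack).
#' @export
train_config <- function(epochs = 30L, steps_per_epoch = 20L,
                         batch_size = 2L, patch_shape = c(8L, 128L, 128L),
                         learning_rate = 1e-4, lr_finetune = 2.5e-5,
                         loss_weights = c(mse = 1, ssim = 0.1), seed = 1L,
                         grad_clip = 1.0, ssim_window = 7L,
                         val_tiling = NULL) {
  chk <- function(cond, msg) fa_assert(cond, msg, "faunet_config_error")
  chk(epochs >= 1, "epochs must be >= 1")
  chk(steps_per_epoch >= 1, "steps_per_epoch must be >= 1")
  chk(batch_size >= 1, "batch_size must be >= 1")
  chk(length(patch_shape) == 3 && patch_shape[1] >= 1 &&
        all(patch_shape[2:3] >= 8), "patch dims must be >= (1, 8, 8)")
  chk(all(loss_weights[c("mse", "ssim")] >= 0) &&
        sum(loss_weights[c("mse", "ssim")]) > 0,
      "loss weights must be >= 0 and not both zero")
  structure(list(epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 batch_size = as.integer(batch_size),
                 patch_shape = as.integer(patch_shape),
                 learning_rate = learning_rate, lr_finetune = lr_finetune,
                 loss_weights = loss_weights, seed = as.integer(seed),
                 grad_clip = grad_clip, ssim_window = as.integer(ssim_window),
                 val_tiling = val_tiling),
            class = "faunet_train_config")
}

#' Sample aligned patch pairs from a stack pair
#'
#' Positions are uniform, identical for the low and high member; the pair
#' is first normalized from the low member's percentile statistics.
#'
#' @param pair a [stack_pair].
#' @param patch_shape `(F_p, H_p, W_p)`.
#' @param n number of patches.
#' @param seed integer seed.
#' @param normalize normalize the pair first (the training default).
#' @return list of `list(low =, high =, offset = c(f, h, w))` with patch
#'   arrays `[C, F_p, H_p, W_p]`.
#' @export
sample_patches <- function(pair, patch_shape, n, seed = 1L,
                           normalize = TRUE) {
  fa_assert(inherits(pair, "faunet_pair"), "expected a stack_pair")
  if (normalize) pair <- normalize_pair(pair)$pair
  d <- dim(pair$low$voxels)  # C F H W
  fp <- min(patch_shape[1], d[2]); hp <- patch_shape[2]; wp <- patch_shape[3]
  fa_assert(hp <= d[3] && wp <= d[4],
            "patch larger than the stack spatially", "faunet_config_error")
  offs <- with_seed(seed, {
    cbind(f = sample.int(d[2] - fp + 1L, n, replace = TRUE),
          h = sample.int(d[3] - hp + 1L, n, replace = TRUE),
          w = sample.int(d[4] - wp + 1L, n, replace = TRUE))
  })
  lapply(seq_len(n), function(i) {
    f0 <- offs[i, 1]; h0 <- offs[i, 2]; w0 <- offs[i, 3]
    list(low = pair$low$voxels[, f0:(f0 + fp - 1), h0:(h0 + hp - 1),
                               w0:(w0 + wp - 1), drop = FALSE],
         high = pair$high$voxels[, f0:(f0 + fp - 1), h0:(h0 + hp - 1),
                                 w0:(w0 + wp - 1), drop = FALSE],
         offset = offs[i, ])
  })
}

## ---- internal training machinery -----------------------------------------

## load + normalize all pairs of a split into internal-layout arrays
.load_split_internal <- function(manifest, split) {
  m <- manifest_split(manifest, split)
  lapply(seq_len(nrow(m$entries)), function(i) {
    pr <- load_pair(m, i)
    np <- normalize_pair(pr)$pair
    list(low = aperm(np$low$voxels, c(3, 4, 1, 2)),   # (H, W, C, F)
         high = aperm(np$high$voxels, c(3, 4, 1, 2)),
         raw_low = pr$low, raw_high = pr$high,
         pair_id = pr$pair_id)
  })
}

.sample_batch <- function(pairs, patch, batch, seed) {
  d1 <- dim(pairs[[1]]$low)
  fp <- min(patch[1], d1[4]); hp <- patch[2]; wp <- patch[3]
  C <- d1[3]
  x <- array(0, dim = c(hp, wp, C, fp, batch))
  t <- array(0, dim = c(hp, wp, C, fp, batch))
  with_seed(seed, {
    for (b in seq_len(batch)) {
      p <- pairs[[sample.int(length(pairs), 1L)]]
      d <- dim(p$low)
      fa_assert(hp <= d[1] && wp <= d[2],
                "patch larger than the stack spatially",
                "faunet_config_error")
      f0 <- sample.int(d[4] - fp + 1L, 1L)
      h0 <- sample.int(d[1] - hp + 1L, 1L)
      w0 <- sample.int(d[2] - wp + 1L, 1L)
      x[, , , , b] <- p$low[h0:(h0 + hp - 1), w0:(w0 + wp - 1), ,
                            f0:(f0 + fp - 1), drop = FALSE]
      t[, , , , b] <- p$high[h0:(h0 + hp - 1), w0:(w0 + wp - 1), ,
                             f0:(f0 + fp - 1), drop = FALSE]
    }
  })
  list(x = x, t = t)
}

.adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

.adam_step <- function(state, w, g, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(w = w - lr * mhat / (sqrt(vhat) + eps), state = state)
}

.train_loop <- function(model, train_pairs, val_pairs, tc, lr) {
  skel <- model$weights
  w <- flatten_params(skel)
  st <- .adam_new(length(w))
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_psnr = numeric())
  for (ep in seq_len(tc$epochs)) {
    losses <- numeric(tc$steps_per_epoch)
    for (s in seq_len(tc$steps_per_epoch)) {
      bseed <- derive_seed(tc$seed, 7L, ep, s)
      bt <- .sample_batch(train_pairs, tc$patch_shape, tc$batch_size, bseed)
      model$weights <- unflatten_params(w, skel)
      fwd <- unet_fw(bt$x, model, keep = TRUE)
      lr_ <- loss_int(fwd$y, bt$t, tc$loss_weights, tc$ssim_window,
                      grad = TRUE)
      if (!is.finite(lr_$value))
        fa_stop(sprintf("non-finite loss at epoch %d step %d (batch seed %d)",
                        ep, s, bseed), "faunet_numeric_error")
      losses[s] <- lr_$value
      bw <- unet_bw(fwd$cache, lr_$dx, model)
      g <- flatten_params(bw$grads)
      gn <- sqrt(sum(g^2))
      if (is.finite(tc$grad_clip) && gn > tc$grad_clip)
        g <- g * (tc$grad_clip / gn)
      up <- .adam_step(st, w, g, lr)
      w <- up$w; st <- up$state
    }
    model$weights <- unflatten_params(w, skel)
    vl <- NA_real_; vp <- NA_real_
    if (length(val_pairs) > 0) {
      vls <- vapply(val_pairs, function(p) {
        out <- .infer_stack(model, p$raw_low, tc$val_tiling)
        c(mean((out$voxels - p$raw_high$voxels)^2),
          psnr(out, p$raw_high, data_range = 1))
      }, numeric(2))
      vl <- mean(vls[1, ]); vp <- mean(vls[2, ])
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_loss = vl, val_psnr = vp))
    log_info(sprintf("epoch %d/%d  train_loss %.5f  val_psnr %s",
                     ep, tc$epochs, mean(losses),
                     if (is.na(vp)) "-" else sprintf("%.2f dB", vp)))
  }
  model$weights <- unflatten_params(w, skel)
  list(model = model, history = hist)
}

.checkpoint <- function(model, train_config, history, stage,
                        parent_id = NULL) {
  structure(list(format_version = 1L, model = model,
                 train_config = train_config, history = history,
                 stage = stage, parent_id = parent_id),
            class = "faunet_checkpoint")
}

checkpoint_hash <- function(ck) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(ck$model$weights, tf)
  unname(tools::md5sum(tf))
}

#' Train a backbone model on pooled data
#'
#' Iterates Adam over random patch batches from the manifest's train
#' split, with per-epoch validation by full-stack tiled inference on the
#' val split.  Fully deterministic given `train_config$seed`.
#'
#' @param manifest a [manifest] with at least one train entry.
#' @param model_config a [model_config].
#' @param train_config a [train_config].
#' @return a `faunet_checkpoint` with `stage = "backbone"` and the full
#'   per-epoch history.
#' @export
train_backbone <- function(manifest, model_config, train_config) {
  train_pairs <- .load_split_internal(manifest, "train")
  fa_assert(length(train_pairs) > 0, "manifest has no train entries",
            "faunet_config_error")
  val_pairs <- .load_split_internal(manifest, "val")
  model <- init_model(model_config, train_config$seed)
  log_info(sprintf("backbone training: %d train / %d val pairs, %d epochs",
                   length(train_pairs), length(val_pairs),
                   train_config$epochs))
  r <- .train_loop(model, train_pairs, val_pairs, train_config,
                   train_config$learning_rate)
  .checkpoint(r$model, train_config, r$history, "backbone")
}

#' Fine-tune a backbone on a few new pairs
#'
#' All weights start from the backbone and all remain trainable; only the
#' learning rate is reduced (`lr_finetune`).
#'
#' @param backbone a backbone `faunet_checkpoint`.
#' @param manifest a [manifest] for the new experiment (typically 5-20
#'   train pairs).
#' @param train_config a [train_config]; defaults follow the 30-epoch
#'   few-pair protocol.
#' @return a `faunet_checkpoint` with `stage = "finetuned"` and
#'   `parent_id` set to the backbone weight hash.
#' @export
finetune <- function(backbone, manifest, train_config) {
  fa_assert(inherits(backbone, "faunet_checkpoint"), "expected a checkpoint",
            "faunet_config_error")
  train_pairs <- .load_split_internal(manifest, "train")
  fa_assert(length(train_pairs) > 0, "manifest has no train entries",
            "faunet_config_error")
  fa_assert(dim(train_pairs[[1]]$low)[3] == backbone$model$config$in_channels,
            "manifest channel count does not match the backbone",
            "faunet_config_error")
  val_pairs <- .load_split_internal(manifest, "val")
  log_info(sprintf("fine-tuning: %d train pairs, %d epochs",
                   length(train_pairs), train_config$epochs))
  r <- .train_loop(backbone$model, train_pairs, val_pairs, train_config,
                   train_config$lr_finetune)
  .checkpoint(r$model, train_config, r$history, "finetuned",
              parent_id = checkpoint_hash(backbone))
}

## ---- tiled inference ------------------------------------------------------

#' Tiling specification for inference
#'
#' @param tile `(F_t, H_t, W_t)` tile size; axes larger than the stack
#'   are clipped.  Frame chunks are disjoint; spatial tiles overlap.
#' @param overlap overlap in pixels per spatial axis.
#' @param blend only `"feather"` (linear ramps, normalized to sum to 1).
#' @export
tiling_spec <- function(tile = c(8L, 64L, 64L), overlap = 8L,
                        blend = "feather") {
  fa_assert(length(tile) == 3 && all(tile >= 1), "tile must be (F, H, W)",
            "faunet_config_error")
  fa_assert(overlap >= 0 && 2 * overlap < tile[2] && 2 * overlap < tile[3],
            "tile must be larger than twice the overlap",
            "faunet_config_error")
  fa_assert(identical(blend, "feather"), "only feather blending is supported",
            "faunet_config_error")
  structure(list(tile = as.integer(tile), overlap = as.integer(overlap),
                 blend = blend), class = "faunet_tiling_spec")
}

.tile_starts <- function(size, tile, overlap) {
  if (tile >= size) return(list(starts = 1L, tile = size))
  step <- tile - overlap
  starts <- seq(1L, size - tile + 1L, by = step)
  if (starts[length(starts)] + tile - 1L < size)
    starts <- c(starts, size - tile + 1L)
  list(starts = as.integer(starts), tile = tile)
}

.ramp_weights <- function(start, tile, size, overlap) {
  w <- rep(1, tile)
  if (overlap > 0) {
    ramp <- seq_len(overlap) / (overlap + 1)
    if (start > 1) w[seq_len(overlap)] <- ramp
    if (start + tile - 1 < size) w[tile + 1 - seq_len(overlap)] <- ramp
  }
  w
}

## internal single-channel-model inference on an ImageStack (raw scale)
.infer_stack <- function(model, stack, tiling = NULL) {
  d <- dim(stack$voxels)  # C F H W
  C <- d[1]
  mc <- model$config$in_channels
  if (C != mc) {
    fa_assert(mc == 1L,
              "stack channel count does not match the model",
              "faunet_config_error")
    ## process stains one at a time
    out <- stack
    for (c in seq_len(C)) {
      sub <- stack
      sub$voxels <- stack$voxels[c, , , , drop = FALSE]
      out$voxels[c, , , ] <- .infer_stack(model, sub, tiling)$voxels
    }
    return(out)
  }
  if (is.null(tiling))
    tiling <- tiling_spec(tile = c(d[2], d[3], d[4]), overlap = 0L)
  nrm <- normalize_stack(stack, clip = FALSE)
  x <- aperm(nrm$stack$voxels, c(3, 4, 1, 2))     # (H, W, C, F)
  H <- d[3]; W <- d[4]; F <- d[2]
  ft <- min(tiling$tile[1], F)
  th <- min(tiling$tile[2], H); tw <- min(tiling$tile[3], W)
  ov <- min(tiling$overlap, th - 1L, tw - 1L)
  gh <- .tile_starts(H, th, ov); gwd <- .tile_starts(W, tw, ov)
  gf <- .tile_starts(F, ft, 0L)
  num <- array(0, dim = c(H, W, 1, F))
  den <- array(0, dim = c(H, W, 1, F))
  ## seam reporting only matters when spatial tiles overlap
  track_seams <- length(gh$starts) > 1 || length(gwd$starts) > 1
  if (track_seams) {
    pmin_ <- array(Inf, dim = c(H, W, 1, F))
    pmax_ <- array(-Inf, dim = c(H, W, 1, F))
  }
  for (f0 in gf$starts) {
    fr <- f0:min(f0 + gf$tile - 1L, F)
    for (h0 in gh$starts) {
      hr <- h0:(h0 + gh$tile - 1L)
      wh <- .ramp_weights(h0, gh$tile, H, ov)
      for (w0 in gwd$starts) {
        wr <- w0:(w0 + gwd$tile - 1L)
        ww <- .ramp_weights(w0, gwd$tile, W, ov)
        xt <- x[hr, wr, , fr, drop = FALSE]
        dim(xt) <- c(length(hr), length(wr), 1, length(fr), 1)
        yt <- unet_fw(xt, model, keep = FALSE)$y
        wgt <- outer(wh, ww)
        for (fi in seq_along(fr)) {
          num[hr, wr, 1, fr[fi]] <- num[hr, wr, 1, fr[fi]] +
            wgt * yt[, , 1, fi, 1]
          den[hr, wr, 1, fr[fi]] <- den[hr, wr, 1, fr[fi]] + wgt
          if (track_seams) {
            pmin_[hr, wr, 1, fr[fi]] <- pmin(pmin_[hr, wr, 1, fr[fi]],
                                             yt[, , 1, fi, 1])
            pmax_[hr, wr, 1, fr[fi]] <- pmax(pmax_[hr, wr, 1, fr[fi]],
                                             yt[, , 1, fi, 1])
          }
        }
      }
    }
  }
  if (track_seams) {
    seam <- pmax_ - pmin_
    log_info(sprintf(
      "tiled inference: max discrepancy between overlapping tiles %.3g",
      max(seam)))
  }
  yn <- num / den
  out <- stack
  out$voxels <- aperm(yn, c(3, 4, 1, 2))
  denormalize_stack(out, nrm$params)
}

#' Denoise a stack with a trained model
#'
#' The stack is percentile-normalized from its own statistics (without
#' clipping, so the map is exactly invertible), processed in overlapping
#' tiles whose predictions are feather-blended with linear ramps
#' normalized to sum to one, then denormalized.  Output shape equals
#' input shape.  Multi-stain stacks are processed channel-by-channel when
#' the model has one input channel.
#'
#' @param checkpoint a `faunet_checkpoint` (or a bare `faunet_model`).
#' @param stack an [image_stack].
#' @param tiling a [tiling_spec], or `NULL` for a single tile covering
#'   the stack.
#' @return the denoised [image_stack].
#' @export
infer <- function(checkpoint, stack, tiling = NULL) {
  model <- if (inherits(checkpoint, "faunet_checkpoint"))
    checkpoint$model else checkpoint
  fa_assert(inherits(model, "faunet_model"),
            "expected a checkpoint or model", "faunet_config_error")
  stack <- as_image_stack(stack)
  .infer_stack(model, stack, tiling)
}
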