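## The frame-attention U-net: pre-conv channel lift, n_down_levels encoder
## stages (cells then stride-2 conv doubling channels), matching decoder
## stages (2x nearest upsample + conv halving channels, skip concatenation,
## merge conv, cells), a zero-initialized post-conv back to the input
## channel count, and a long skip connection so the untrained network is
## exactly the identity.

#' Model hyper-parameters
#'
#' @param in_channels input (stain) channels the model processes at once.
#' @param base_channels channel width after the pre-conv lift; doubles at
#'   every downsampling stage.
#' @param n_down_levels number of stride-2 stages (and matching upsample
#'   stages).
#' @param cells_per_level transformer cells per U-net level.
#' @param n_heads attention heads; must divide `base_channels`.
#' @param proj_kernel odd kernel size of all projection convs.
#' @param mixer_kernel odd kernel size of the mixer convs.
#' @param mixer_expansion hidden-width multiplier of the mixer.
#' @param attention_mode `"pooled"` (one F x F score matrix per head,
#'   linear in pixels) or `"pixelwise"` (an F x F softmax per pixel).
#' @param norm,activation fixed to `"instance"` / `"gelu"`.
#' @return a validated `faunet_model_config`.
#' @export
model_config <- function(in_channels = 1L, base_channels = 32L,
                         n_down_levels = 2L, cells_per_level = 4L,
                         n_heads = 4L, proj_kernel = 3L, mixer_kernel = 3L,
                         mixer_expansion = 2L,
                         attention_mode = c("pooled", "pixelwise"),
                         norm = "instance", activation = "gelu") {
  attention_mode <- match.arg(attention_mode)
  chk <- function(cond, msg) fa_assert(cond, msg, "faunet_config_error")
  chk(in_channels >= 1, "in_channels must be >= 1")
  chk(base_channels >= 1, "base_channels must be >= 1")
  chk(n_down_levels >= 1, "n_down_levels must be >= 1")
  chk(cells_per_level >= 1, "cells_per_level must be >= 1")
  chk(base_channels %% n_heads == 0,
      "base_channels must be divisible by n_heads")
  chk(proj_kernel %% 2 == 1, "proj_kernel must be odd")
  chk(mixer_kernel %% 2 == 1, "mixer_kernel must be odd")
  chk(mixer_expansion >= 1, "mixer_expansion must be >= 1")
  chk(identical(norm, "instance"), "only instance norm is supported")
  chk(identical(activation, "gelu"), "only gelu activation is supported")
  structure(list(
    in_channels = as.integer(in_channels),
    base_channels = as.integer(base_channels),
    n_down_levels = as.integer(n_down_levels),
    cells_per_level = as.integer(cells_per_level),
    n_heads = as.integer(n_heads),
    proj_kernel = as.integer(proj_kernel),
    mixer_kernel = as.integer(mixer_kernel),
    mixer_expansion = as.integer(mixer_expansion),
    attention_mode = attention_mode, norm = norm, activation = activation
  ), class = "faunet_model_config")
}

#' Initialize model parameters
#'
#' Convolution weights are drawn fan-in-scaled (He normal); the post-conv
#' is zero-initialized so the initial network is the identity through the
#' long skip connection, which stabilizes both backbone training and
#' fine-tuning.
#'
#' @param config a [model_config].
#' @param seed integer; the draw is deterministic given the seed.
#' @return a `faunet_model` holding the config and the weight tree.
#' @export
init_model <- function(config, seed = 1L) {
  fa_assert(inherits(config, "faunet_model_config"),
            "config must come from model_config()", "faunet_config_error")
  kp <- config$proj_kernel; km <- config$mixer_kernel
  L <- config$n_down_levels; e <- config$mixer_expansion
  weights <- with_seed(seed, {
    w <- list()
    w$pre <- conv_params(kp, config$in_channels, config$base_channels)
    w$down <- lapply(seq_len(L), function(l) {
      c <- config$base_channels * 2^(l - 1)
      list(cells = lapply(seq_len(config$cells_per_level), function(i)
        cell_init(kp, km, c, c, e)),
        ds = conv_params(kp, c, 2 * c))
    })
    w$up <- lapply(seq_len(L), function(j) {
      cj <- config$base_channels * 2^(L - j + 1)
      list(us = conv_params(kp, cj, cj %/% 2),
           merge = conv_params(kp, cj, cj %/% 2),
           cells = lapply(seq_len(config$cells_per_level), function(i)
             cell_init(kp, km, cj %/% 2, cj %/% 2, e)))
    })
    w$post <- conv_params(kp, config$base_channels, config$in_channels,
                          init = "zero")
    w
  })
  structure(list(config = config, weights = weights), class = "faunet_model")
}

#' @export
print.faunet_model <- function(x, ...) {
  cat(sprintf(
    "<faunet_model> C=%d base=%d levels=%d cells/level=%d heads=%d (%s attention), %d parameters\n",
    x$config$in_channels, x$config$base_channels, x$config$n_down_levels,
    x$config$cells_per_level, x$config$n_heads, x$config$attention_mode,
    length(flatten_params(x$weights))))
  invisible(x)
}

#' Count learnable parameters of a configuration
#' @param config a [model_config].
#' @return total number of learnable scalars.
#' @export
parameter_count <- function(config) {
  length(flatten_params(init_model(config, seed = 1L)$weights))
}

## ---- internal forward / backward on (H, W, C, F, B) -----------------------

unet_fw <- function(x, model, keep = FALSE) {
  cfg <- model$config; w <- model$weights
  fa_assert(all(is.finite(x)), "non-finite values in network input")
  fa_assert(dim(x)[3] == cfg$in_channels,
            "input channel count does not match the model",
            "faunet_config_error")
  L <- cfg$n_down_levels
  pad <- pad_to_multiple(x, 2^L)
  xp <- pad$y
  cache <- if (keep) list(pad = pad, xp = xp) else NULL
  h <- conv_fw(xp, w$pre)
  skips <- vector("list", L)
  if (keep) cache$down <- vector("list", L)
  for (l in seq_len(L)) {
    cl <- if (keep) list(cells = vector("list", cfg$cells_per_level)) else NULL
    for (ci in seq_len(cfg$cells_per_level)) {
      r <- cell_fw(h, w$down[[l]]$cells[[ci]], cfg, keep)
      if (keep) cl$cells[[ci]] <- r$cache
      h <- r$y
    }
    skips[[l]] <- h
    if (keep) cl$ds_x <- h
    h <- conv_fw(h, w$down[[l]]$ds, stride = 2L)
    if (keep) cache$down[[l]] <- cl
  }
  if (keep) cache$up <- vector("list", L)
  for (j in seq_len(L)) {
    ul <- if (keep) list(cells = vector("list", cfg$cells_per_level)) else NULL
    hu <- upsample2(h)
    if (keep) ul$us_x <- hu
    h2 <- conv_fw(hu, w$up[[j]]$us)
    hc <- concat_c(h2, skips[[L - j + 1]])
    if (keep) ul$merge_x <- hc
    h <- conv_fw(hc, w$up[[j]]$merge)
    for (ci in seq_len(cfg$cells_per_level)) {
      r <- cell_fw(h, w$up[[j]]$cells[[ci]], cfg, keep)
      if (keep) ul$cells[[ci]] <- r$cache
      h <- r$y
    }
    if (keep) cache$up[[j]] <- ul
  }
  if (keep) cache$post_x <- h
  y <- conv_fw(h, w$post)
  out <- pad_crop(y + xp, pad)
  list(y = out, cache = cache)
}

unet_bw <- function(cache, dout, model) {
  cfg <- model$config; w <- model$weights
  L <- cfg$n_down_levels
  dz <- pad_bw(dout, cache$pad)        # grad at padded resolution
  dxp_skip <- dz                        # long skip branch
  r_post <- conv_bw(cache$post_x, w$post, dz)
  dh <- r_post$dx
  gw <- list(post = list(w = r_post$dw, b = r_post$db))
  gw$up <- vector("list", L)
  dskips <- vector("list", L)
  for (j in rev(seq_len(L))) {
    ul <- cache$up[[j]]
    gcells <- vector("list", cfg$cells_per_level)
    for (ci in rev(seq_len(cfg$cells_per_level))) {
      r <- cell_bw(ul$cells[[ci]], dh, w$up[[j]]$cells[[ci]], cfg)
      gcells[[ci]] <- r$grads
      dh <- r$dx
    }
    r_mg <- conv_bw(ul$merge_x, w$up[[j]]$merge, dh)
    c_half <- dim(ul$us_x)[3] %/% 2
    sp <- split_c(r_mg$dx, c_half)
    dskips[[L - j + 1]] <- sp$b
    r_us <- conv_bw(ul$us_x, w$up[[j]]$us, sp$a)
    dh <- upsample2_bw(r_us$dx)
    gw$up[[j]] <- list(us = list(w = r_us$dw, b = r_us$db),
                       merge = list(w = r_mg$dw, b = r_mg$db),
                       cells = gcells)
  }
  gw$down <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dl <- cache$down[[l]]
    r_ds <- conv_bw(dl$ds_x, w$down[[l]]$ds, dh, stride = 2L)
    dh <- r_ds$dx + dskips[[l]]
    gcells <- vector("list", cfg$cells_per_level)
    for (ci in rev(seq_len(cfg$cells_per_level))) {
      r <- cell_bw(dl$cells[[ci]], dh, w$down[[l]]$cells[[ci]], cfg)
      gcells[[ci]] <- r$grads
      dh <- r$dx
    }
    gw$down[[l]] <- list(cells = gcells, ds = list(w = r_ds$dw, b = r_ds$db))
  }
  r_pre <- conv_bw(cache$xp, w$pre, dh)
  gw$pre <- list(w = r_pre$dw, b = r_pre$db)
  dxp <- r_pre$dx + dxp_skip
  dx <- pad_fold(dxp, cache$pad)
  ## reorder to match the weight-tree layout used by the optimizer
  grads <- list(pre = gw$pre, down = gw$down, up = gw$up, post = gw$post)
  list(dx = dx, grads = grads)
}

## ---- public API on the [B, C, F, H, W] convention -------------------------

to_internal <- function(x) {
  fa_assert(is.numeric(x) && length(dim(x)) == 5,
            "expected a 5-d array [B, C, F, H, W]")
  aperm(x, c(4, 5, 2, 3, 1))
}

to_public <- function(x) aperm(x, c(5, 3, 4, 1, 2))

#' Run the U-net forward
#'
#' Output shape always equals input shape: H and W not divisible by
#' `2^n_down_levels` are reflect-padded internally and cropped back, and
#' the frame axis is never resampled.
#'
#' @param model a `faunet_model` from [init_model] (or a checkpoint's
#'   `$model`).
#' @param x 5-d array `[B, C, F, H, W]`.
#' @return array of the same shape.
#' @export
model_forward <- function(model, x) {
  fa_assert(inherits(model, "faunet_model"), "expected a faunet_model")
  to_public(unet_fw(to_internal(x), model, keep = FALSE)$y)
}

#' Convolutional key/query/value projection of one cell
#'
#' Each projection is an independent per-frame 2D convolution; no
#' cross-frame mixing happens in the projection itself.
#'
#' @param x 5-d array `[B, C', F, H, W]` (channel count must match the
#'   cell's width).
#' @param cell_params one cell's parameter list (e.g.
#'   `model$weights$down[[1]]$cells[[1]]`).
#' @return `list(K = , Q = , V = )` of arrays shaped like `x`.
#' @export
project_kqv <- function(x, cell_params) {
  xi <- to_internal(x)
  list(K = to_public(conv_fw(xi, cell_params$k)),
       Q = to_public(conv_fw(xi, cell_params$q)),
       V = to_public(conv_fw(xi, cell_params$v)))
}

#' Multi-head attention across frames
#'
#' In `"pooled"` mode the score for frames (t, s) of head h is
#' `sum_{c in h, x, y} Q[c,t,x,y] K[c,s,x,y] / sqrt(d_h H W)`, softmaxed
#' over s — a single F x F matrix per head, so cost is linear in pixels.
#' `"pixelwise"` keeps an F x F softmax at every pixel.
#'
#' @param K,Q,V 5-d arrays `[B, C, F, H, W]` of identical shape.
#' @param n_heads number of heads (must divide C).
#' @param mode `"pooled"` or `"pixelwise"`.
#' @param return_scores also return the attention matrices (pooled mode:
#'   one F x F matrix per batch element and head).
#' @return the attended tensor, or a list with `y` and `scores`.
#' @export
frame_attention <- function(K, Q, V, n_heads = 1L,
                            mode = c("pooled", "pixelwise"),
                            return_scores = FALSE) {
  mode <- match.arg(mode)
  fa_assert(identical(dim(K), dim(Q)) && identical(dim(K), dim(V)),
            "K, Q, V must have identical shapes")
  r <- attn_fw(to_internal(K), to_internal(Q), to_internal(V), n_heads,
               mode, keep = return_scores)
  if (!return_scores) return(to_public(r$y))
  scores <- if (mode == "pooled")
    lapply(r$cache$mats, function(m) m$A) else
      lapply(r$cache$mats, function(m) m$A)
  list(y = to_public(r$y), scores = scores)
}

#' Run one transformer cell forward
#'
#' @param x 5-d array `[B, C', F, H, W]`.
#' @param cell_params one cell's parameter list.
#' @param config the [model_config] (for heads and attention mode).
#' @return array `[B, C_cell, F, H, W]`.
#' @export
cell_forward <- function(x, cell_params, config) {
  to_public(cell_fw(to_internal(x), cell_params, config, keep = FALSE)$y)
}
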