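# Shared fixtures.  Everything is generated in code under tempdir(); the
# heavier training artifacts used by several acceptance criteria are built
# lazily once per session and cached in .fx.

fa_log_setup("warn")

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(in_channels = 1L, base_channels = 4L, n_down_levels = 2L,
         cells_per_level = 1L, n_heads = 2L), list(...))
  do.call(model_config, args)
}

smoke_config <- function(...) {
  args <- utils::modifyList(
    list(in_channels = 1L, base_channels = 8L, n_down_levels = 2L,
         cells_per_level = 1L, n_heads = 2L), list(...))
  do.call(model_config, args)
}

## randomize every weight of a model (the default init zeroes the
## post-conv, which identity-propagates; tests of generic behaviour need
## fully random weights)
randomize_model <- function(model, seed = 1, sd = 0.1) {
  v <- faunet:::flatten_params(model$weights)
  v <- with_seed_test(seed, stats::rnorm(length(v), sd = sd))
  model$weights <- faunet:::unflatten_params(v, model$weights)
  model
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

random_batch <- function(dims, seed = 1) {
  with_seed_test(seed, array(stats::rnorm(prod(dims)), dims))
}

## the stated smoke-scale noise regime: ~18-19 dB single-shot input PSNR,
## high member from a 32-repeat average (line-average analog)
fx_low_noise <- function() noise_params(15, 1, 1)
fx_high_noise <- function() noise_params(15, 1, 32)

fx_filament_manifest <- function() fx_get("fil_manifest", function() {
  dir <- file.path(tempdir(), "fx_filaments")
  make_pair_dataset(
    26, phantom_spec("filaments", c(4, 48, 48), density = 6, seed = 1),
    fx_low_noise(), fx_high_noise(), dir, seed = 11,
    split_counts = c(train = 20, val = 2, test = 4))
})

fx_blob_manifest <- function() fx_get("blob_manifest", function() {
  dir <- file.path(tempdir(), "fx_blobs")
  make_pair_dataset(
    9, phantom_spec("blobs", c(4, 48, 48), density = 6, seed = 2),
    fx_low_noise(), fx_high_noise(), dir, seed = 21,
    split_counts = c(train = 5, val = 1, test = 3))
})

fx_smoke_train_config <- function(...) {
  args <- utils::modifyList(
    list(epochs = 12L, steps_per_epoch = 20L, batch_size = 2L,
         patch_shape = c(4L, 32L, 32L), learning_rate = 3e-3,
         lr_finetune = 1e-3, seed = 5L), list(...))
  do.call(train_config, args)
}

## the backbone shared by the learning/adaptation/robustness criteria
fx_backbone <- function() fx_get("backbone", function() {
  train_backbone(fx_filament_manifest(), smoke_config(),
                 fx_smoke_train_config())
})

## average series in the blob (fine-tune) domain
fx_series <- function() fx_get("series", function() {
  make_average_series(
    phantom_spec("blobs", c(4, 48, 48), density = 6, seed = 31),
    noise_params(15, 1), N = 64L, seed = 41)
})

## brute-force connected components (8-connectivity) above a threshold
count_components <- function(img, thr) {
  lab <- matrix(0L, nrow(img), ncol(img))
  mask <- img > thr
  comp <- 0L
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      comp <- comp + 1L
      queue <- list(c(i, j)); lab[i, j] <- comp
      while (length(queue) > 0) {
        p <- queue[[1]]; queue[[1]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          qi <- p[1] + di; qj <- p[2] + dj
          if (qi >= 1 && qi <= nrow(img) && qj >= 1 && qj <= ncol(img) &&
              mask[qi, qj] && lab[qi, qj] == 0L) {
            lab[qi, qj] <- comp
            queue[[length(queue) + 1L]] <- c(qi, qj)
          }
        }
      }
    }
  }
  comp
}

## brute-force PSNR: explicit voxel loop
psnr_bruteforce <- function(x, ref, data_range = 1) {
  a <- if (inherits(x, "faunet_stack")) x$voxels else x
  b <- if (inherits(ref, "faunet_stack")) ref$voxels else ref
  se <- 0; n <- 0
  for (i in seq_along(a)) { se <- se + (a[i] - b[i])^2; n <- n + 1 }
  if (se == 0) return(Inf)
  10 * log10(data_range^2 / (se / n))
}

## brute-force volumetric SSIM: voxel-by-voxel loop with an explicit 3D
## Gaussian window (sigma 1.5), symmetric edge padding, window clipped per
## axis to the largest odd size <= that axis
ssim3d_bruteforce <- function(x, ref, window = 11, k1 = 0.01, k2 = 0.03,
                              data_range = 1) {
  a <- if (inherits(x, "faunet_stack")) x$voxels else x
  b <- if (inherits(ref, "faunet_stack")) ref$voxels else ref
  C <- dim(a)[1]
  mirror <- function(p, n) {
    if (p < 1) p <- 1 - p
    if (p > n) p <- 2 * n + 1 - p
    p
  }
  score_vol <- function(va, vb) {
    d <- dim(va)
    ws <- vapply(d, function(n) {
      w <- min(window, if (n %% 2 == 1) n else n - 1); max(w, 1)
    }, numeric(1))
    rs <- (ws - 1) / 2
    g1 <- lapply(rs, function(r)
      { k <- exp(-((-r):r)^2 / (2 * 1.5^2)); k / sum(k) })
    C1 <- (k1 * data_range)^2; C2 <- (k2 * data_range)^2
    tot <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
      mx <- 0; my <- 0; sxx <- 0; syy <- 0; sxy <- 0
      for (oi in -rs[1]:rs[1]) for (oj in -rs[2]:rs[2]) for (ol in -rs[3]:rs[3]) {
        w <- g1[[1]][oi + rs[1] + 1] * g1[[2]][oj + rs[2] + 1] *
          g1[[3]][ol + rs[3] + 1]
        pa <- va[mirror(i + oi, d[1]), mirror(j + oj, d[2]),
                 mirror(l + ol, d[3])]
        pb <- vb[mirror(i + oi, d[1]), mirror(j + oj, d[2]),
                 mirror(l + ol, d[3])]
        mx <- mx + w * pa; my <- my + w * pb
        sxx <- sxx + w * pa^2; syy <- syy + w * pb^2; sxy <- sxy + w * pa * pb
      }
      vx <- sxx - mx^2; vy <- syy - my^2; vxy <- sxy - mx * my
      tot <- tot + ((2 * mx * my + C1) * (2 * vxy + C2)) /
        ((mx^2 + my^2 + C1) * (vx + vy + C2))
    }
    tot / prod(d)
  }
  mean(vapply(seq_len(C), function(c) {
    va <- a[c, , , , drop = FALSE]; dim(va) <- dim(a)[2:4]
    vb <- b[c, , , , drop = FALSE]; dim(vb) <- dim(b)[2:4]
    score_vol(va, vb)
  }, numeric(1)))
}
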