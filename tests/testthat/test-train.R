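# training: patch sampling, short training runs, inference plumbing.

test_that("sample_patches pairs positions and covers the stack", {
  sp <- phantom_spec("blobs", c(4, 64, 64), density = 4, seed = 3)
  clean <- make_clean_stack(sp)
  pair <- stack_pair(degrade(clean, fx_low_noise(), 1),
                     degrade(clean, fx_high_noise(), 2), "p")
  ## full-stack patch, n = 1 -> the normalized full pair
  full <- sample_patches(pair, c(4, 64, 64), 1, seed = 1)
  np <- normalize_pair(pair)$pair
  expect_equal(full[[1]]$low, np$low$voxels, tolerance = 1e-12)
  expect_equal(full[[1]]$high, np$high$voxels, tolerance = 1e-12)
  ## identical offsets for both members, and patch content matches them
  ps <- sample_patches(pair, c(2, 32, 32), 20, seed = 2)
  for (p in ps) {
    o <- p$offset
    expect_equal(p$low,
                 np$low$voxels[, o[1]:(o[1] + 1), o[2]:(o[2] + 31),
                               o[3]:(o[3] + 31), drop = FALSE],
                 tolerance = 1e-12)
  }
  ## coverage: 100 patches of 32^2 on 64^2 hit all four quadrants
  ps2 <- sample_patches(pair, c(2, 32, 32), 100, seed = 3)
  hs <- vapply(ps2, function(p) p$offset[2], numeric(1))
  ws <- vapply(ps2, function(p) p$offset[3], numeric(1))
  expect_true(all(table(hs > 16, ws > 16) > 0))
  ## oversized patches rejected
  expect_error(sample_patches(pair, c(2, 128, 32), 1, 1), "larger")
})

test_that("training contracts: history, determinism, error handling", {
  m <- fx_blob_manifest()
  mc <- tiny_config()
  tc <- train_config(epochs = 3, steps_per_epoch = 3, batch_size = 1,
                     patch_shape = c(4, 16, 16), learning_rate = 1e-3,
                     seed = 4)
  ck1 <- train_backbone(m, mc, tc)
  expect_s3_class(ck1, "faunet_checkpoint")
  expect_identical(ck1$stage, "backbone")
  expect_equal(nrow(ck1$history), 3)
  expect_true(all(is.finite(ck1$history$train_loss)))
  expect_true(all(is.finite(ck1$history$val_psnr)))
  ## reproducibility: identical seeds give identical histories
  ck2 <- train_backbone(m, mc, tc)
  expect_equal(ck1$history$val_psnr, ck2$history$val_psnr,
               tolerance = 1e-4)
  expect_identical(faunet:::flatten_params(ck1$model$weights),
                   faunet:::flatten_params(ck2$model$weights))
  ## fine-tuning keeps lineage and validates configs
  tcf <- train_config(epochs = 1, steps_per_epoch = 2, batch_size = 1,
                      patch_shape = c(4, 16, 16), lr_finetune = 1e-4,
                      seed = 6)
  ft <- finetune(ck1, m, tcf)
  expect_identical(ft$stage, "finetuned")
  expect_false(is.null(ft$parent_id))
  expect_equal(nrow(ft$history), 1)
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(patch_shape = c(1, 4, 4)), "patch")
  ## channel-mismatched manifest rejected at finetune time
  ck_c2 <- ck1; ck_c2$model <- init_model(tiny_config(in_channels = 2L), 1)
  expect_error(finetune(ck_c2, m, tcf), "channel")
})

test_that("identity-initialized model propagates through any tiling", {
  model <- init_model(smoke_config(), 13)
  sp <- phantom_spec("filaments", c(4, 40, 44), density = 5, seed = 17)
  st <- degrade(make_clean_stack(sp), fx_low_noise(), 3)
  for (tl in list(NULL, tiling_spec(c(4, 32, 32), 8),
                  tiling_spec(c(2, 16, 16), 4))) {
    out <- infer(model, st, tl)
    expect_identical(dim(out$voxels), dim(st$voxels))
    expect_equal(out$voxels, st$voxels, tolerance = 1e-12)
  }
})

test_that("evaluate_pairs: identity propagation and summary consistency", {
  m <- fx_blob_manifest()
  id_ck <- faunet:::.checkpoint(
    init_model(smoke_config(), 3),
    train_config(epochs = 1, steps_per_epoch = 1, batch_size = 1,
                 patch_shape = c(1, 8, 8)),
    data.frame(epoch = 1, train_loss = 0, val_loss = NA, val_psnr = NA),
    "backbone")
  rep_ <- evaluate_pairs(id_ck, m, "test")
  expect_equal(rep_$per_pair$psnr_output, rep_$per_pair$psnr_input,
               tolerance = 1e-9)
  ## summary recomputable from the per-pair rows
  expect_equal(rep_$summary$mean[rep_$summary$metric == "psnr_input"],
               mean(rep_$per_pair$psnr_input), tolerance = 1e-12)
  expect_equal(rep_$summary$sd[rep_$summary$metric == "ssim3d_output"],
               stats::sd(rep_$per_pair$ssim3d_output), tolerance = 1e-12)
  ## purity: repeated invocation yields identical reports
  rep2 <- evaluate_pairs(id_ck, m, "test")
  expect_identical(rep_$per_pair, rep2$per_pair)
  expect_error(evaluate_pairs(id_ck, manifest(), "test"), "no entries")
})

test_that("inference handles the scaled-down large-stack shape contract", {
  model <- init_model(tiny_config(), 2)
  st <- image_stack(array(stats::runif(1 * 10 * 60 * 60), c(1, 10, 60, 60)))
  out <- infer(model, st, tiling_spec(c(4, 32, 32), 8))
  expect_identical(dim(out$voxels), c(1L, 10L, 60L, 60L))
  ## multi-stain stacks are processed channel-by-channel with a C=1 model
  st2 <- image_stack(array(stats::runif(2 * 2 * 24 * 24), c(2, 2, 24, 24)))
  out2 <- infer(model, st2)
  expect_identical(dim(out2$voxels), dim(st2$voxels))
  expect_equal(out2$voxels, st2$voxels, tolerance = 1e-12)
  ## invalid tilings rejected
  expect_error(tiling_spec(c(4, 16, 16), 8), "overlap")
})

test_that("checkpoints round-trip through disk with config-only inspection", {
  d <- withr::local_tempdir()
  m <- fx_blob_manifest()
  tc <- train_config(epochs = 1, steps_per_epoch = 2, batch_size = 1,
                     patch_shape = c(4, 16, 16), seed = 2)
  ck <- train_backbone(m, tiny_config(), tc)
  p <- file.path(d, "m.ckpt")
  save_checkpoint(ck, p)
  ck2 <- load_checkpoint(p)
  expect_equal(faunet:::flatten_params(ck2$model$weights),
               faunet:::flatten_params(ck$model$weights))
  info <- checkpoint_info(p)
  expect_identical(info$stage, "backbone")
  expect_equal(info$n_parameters, parameter_count(tiny_config()))
  expect_equal(info$epochs_trained, 1)
  expect_error(load_checkpoint(file.path(d, "missing.ckpt")), "no such")
})
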