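# synth_data: phantoms, Poisson-Gaussian degradation, average series.

test_that("phantom generation is deterministic and respects the spec", {
  for (kind in c("filaments", "blobs", "tubes")) {
    sp <- phantom_spec(kind, c(3, 32, 32), density = 4, seed = 12)
    a <- make_clean_stack(sp)
    b <- make_clean_stack(sp)
    expect_identical(a$voxels, b$voxels)
    expect_identical(dim(a$voxels), c(1L, 3L, 32L, 32L))
    expect_true(min(a$voxels) >= 0 && max(a$voxels) <= 1)
    sp2 <- sp; sp2$seed <- 13L
    expect_false(identical(make_clean_stack(sp2)$voxels, a$voxels))
  }
  expect_error(phantom_spec("blobs", c(3, 32, 32), density = 0), "density")
  expect_error(phantom_spec("blobs", intensity_range = c(0.9, 0.4)),
               "intensity")
})

test_that("a single blob gives one connected bright component per frame", {
  sp <- phantom_spec("blobs", c(3, 40, 40), density = 1, background = 0,
                     seed = 8)
  s <- make_clean_stack(sp)
  for (f in 1:3) {
    img <- s$voxels[1, f, , ]
    expect_equal(count_components(img, max(img) / 2), 1L)
  }
  ## background level is reproduced away from structures (corner voxel)
  spb <- phantom_spec("blobs", c(2, 64, 64), density = 1, background = 0.1,
                      seed = 8)
  sb <- make_clean_stack(spb)
  expect_equal(sb$voxels[1, 1, 1, 1], 0.1, tolerance = 0.02)
})

test_that("degrade reproduces the Poisson-Gaussian moments", {
  const <- image_stack(array(0.5, c(1, 1, 128, 128)))  # 16384 voxels
  np <- noise_params(photon_level = 20, read_sigma = 1, n_average = 1)
  d <- degrade(const, np, seed = 99)
  ## mean: E = 0.5; sd of the MC mean is ~0.0013
  expect_equal(mean(d$voxels), 0.5, tolerance = 0.006)
  ## variance: (alpha*0.5 + sigma_r^2) / alpha^2 = 0.0275, MC rel sd ~1.1%
  expect_equal(stats::var(as.vector(d$voxels)), (20 * 0.5 + 1) / 400,
               tolerance = 0.05)
  ## zero clean, no read noise -> exactly zero
  z <- degrade(image_stack(array(0, c(1, 1, 16, 16))),
               noise_params(10), seed = 1)
  expect_true(all(z$voxels == 0))
  ## very high photon level -> within 1% of clean
  sp <- phantom_spec("blobs", c(1, 32, 32), density = 3, seed = 4)
  cl <- make_clean_stack(sp)
  hi <- degrade(cl, noise_params(1e6), seed = 2)
  expect_lt(max(abs(hi$voxels - cl$voxels)) / max(cl$voxels), 0.01)
  ## determinism and seed sensitivity
  expect_identical(degrade(const, np, 5)$voxels, degrade(const, np, 5)$voxels)
  expect_false(identical(degrade(const, np, 5)$voxels,
                         degrade(const, np, 6)$voxels))
  ## averaging repeats reduces variance ~ 1/n
  d8 <- degrade(const, noise_params(20, 1, 8), seed = 3)
  expect_equal(stats::var(as.vector(d8$voxels)), 0.0275 / 8,
               tolerance = 0.1)
})

test_that("degrade is mean-preserving over repeated draws", {
  sp <- phantom_spec("blobs", c(1, 24, 24), density = 2, seed = 6)
  cl <- make_clean_stack(sp)
  np <- noise_params(10, 0.5)
  M <- 40
  acc <- array(0, dim(cl$voxels))
  for (i in seq_len(M)) acc <- acc + degrade(cl, np, seed = 100 + i)$voxels
  ## per-voxel sd of the M-mean is sqrt(var)/sqrt(M); compare global RMSE
  rmse <- sqrt(mean((acc / M - cl$voxels)^2))
  expect_lt(rmse, 3 * sqrt(mean(cl$voxels / 10 + 0.25 / 100) / M))
})

test_that("average series is a running mean with the stated structure", {
  sp <- phantom_spec("blobs", c(2, 24, 24), density = 3, seed = 9)
  np <- noise_params(15, 1)
  N <- 8L
  se <- make_average_series(sp, np, N, seed = 77)
  expect_length(se$members, N)
  expect_identical(se$ground_truth_index, N)
  shot <- noise_params(15, 1, 1)
  reps <- lapply(seq_len(N), function(n)
    degrade(se$clean, shot, derive_seed(77, n))$voxels)
  ## member 1 is the first raw degradation exactly
  expect_identical(se$members[[1]]$voxels, reps[[1]])
  ## member N is the arithmetic mean of all repeats to machine precision
  expect_equal(se$members[[N]]$voxels, Reduce(`+`, reps) / N,
               tolerance = 1e-12)
  ## running-mean identity: n*member_n - (n-1)*member_{n-1} == repeat_n
  for (n in 2:N) {
    expect_equal(n * se$members[[n]]$voxels -
                   (n - 1) * se$members[[n - 1]]$voxels,
                 reps[[n]], tolerance = 1e-9)
  }
})

test_that("series MSE follows the 1/n law when read noise is absent", {
  sp <- phantom_spec("blobs", c(2, 32, 32), density = 4, seed = 14)
  se <- make_average_series(sp, noise_params(15, 0), N = 64L, seed = 55)
  ns <- c(1, 4, 16, 64)
  mse <- vapply(ns, function(n)
    mean((se$members[[n]]$voxels - se$clean$voxels)^2), numeric(1))
  fit <- stats::lm(mse ~ I(1 / ns))
  expect_gt(stats::coef(fit)[2], 0)
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("make_pair_dataset writes a consistent, deterministic dataset", {
  d1 <- file.path(tempdir(), "ds_det_1")
  d2 <- file.path(tempdir(), "ds_det_2")
  sp <- phantom_spec("blobs", c(2, 32, 32), density = 3, seed = 1)
  m1 <- make_pair_dataset(5, sp, fx_low_noise(), fx_high_noise(), d1,
                          seed = 3, split_counts = c(train = 3, val = 1,
                                                     test = 1))
  expect_equal(nrow(m1$entries), 5)
  expect_length(list.files(d1, pattern = "\\.tif$"), 10)
  ## low precondition enforced
  expect_error(make_pair_dataset(2, sp, fx_high_noise(), fx_low_noise(),
                                 d1, 3), "noisier")
  ## high member is closer to clean than the low member, for every pair
  for (i in 1:5) {
    pr <- load_pair(m1, i)
    clean <- make_clean_stack(phantom_spec("blobs", c(2, 32, 32),
                                           density = 3,
                                           seed = derive_seed(3, i, 1L)))
    expect_gt(psnr(pr$high, clean), psnr(pr$low, clean))
  }
  ## same seed -> byte-identical manifests
  make_pair_dataset(5, sp, fx_low_noise(), fx_high_noise(), d2, seed = 3,
                    split_counts = c(train = 3, val = 1, test = 1))
  expect_identical(readLines(file.path(d1, "manifest.tsv")),
                   readLines(file.path(d2, "manifest.tsv")))
})
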