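# model core: config validation, init, attention, cell, U-net, gradients.

test_that("model_config validates divisibility and kernel parity", {
  expect_s3_class(tiny_config(), "faunet_model_config")
  expect_error(model_config(base_channels = 0), "base_channels")
  expect_error(model_config(base_channels = 6, n_heads = 4), "divisible")
  expect_error(model_config(proj_kernel = 4), "odd")
})

test_that("init_model is deterministic in the seed and zero-inits the post-conv", {
  cfg <- tiny_config()
  m1 <- init_model(cfg, 7)
  m2 <- init_model(cfg, 7)
  expect_identical(m1$weights, m2$weights)
  m3 <- init_model(cfg, 8)
  expect_false(identical(faunet:::flatten_params(m1$weights),
                         faunet:::flatten_params(m3$weights)))
  expect_true(all(m1$weights$post$w == 0))
  ## identity at initialization through the long skip
  x <- random_batch(c(2, 1, 3, 16, 16), seed = 1)
  expect_equal(model_forward(m1, x), x, tolerance = 0)
})

test_that("K/Q/V projections are per-frame convolutions", {
  cfg <- tiny_config()
  cell <- randomize_model(init_model(cfg, 3), 5)$weights$down[[1]]$cells[[1]]
  ## identity kernel, zero bias -> K == x
  idcell <- cell
  k <- dim(idcell$k$w)[1]; c <- dim(idcell$k$w)[3]
  idcell$k$w[] <- 0
  mid <- (k + 1) / 2
  for (ci in seq_len(c)) idcell$k$w[mid, mid, ci, ci] <- 1
  idcell$k$b[] <- 0
  x <- random_batch(c(1, c, 3, 8, 8), seed = 2)
  expect_equal(project_kqv(x, idcell)$K, x, tolerance = 1e-12)
  ## zero input, zero bias -> zero projections
  zcell <- cell; zcell$k$b[] <- 0; zcell$q$b[] <- 0; zcell$v$b[] <- 0
  z <- array(0, c(1, c, 3, 8, 8))
  pz <- project_kqv(z, zcell)
  expect_true(all(pz$K == 0) && all(pz$Q == 0) && all(pz$V == 0))
  ## frame permutation of the input permutes the projections identically
  perm <- c(3, 1, 2)
  p1 <- project_kqv(x, cell)
  p2 <- project_kqv(x[, , perm, , , drop = FALSE], cell)
  expect_equal(p1$Q[, , perm, , , drop = FALSE], p2$Q, tolerance = 1e-12)
})

test_that("frame attention: softmax structure and degenerate cases", {
  ## F = 1: attention matrix is [[1]], output equals V
  K <- random_batch(c(1, 2, 1, 4, 4), 1)
  Q <- random_batch(c(1, 2, 1, 4, 4), 2)
  V <- random_batch(c(1, 2, 1, 4, 4), 3)
  r <- frame_attention(K, Q, V, n_heads = 2, return_scores = TRUE)
  expect_equal(r$y, V, tolerance = 1e-12)
  expect_equal(r$scores[[1]], matrix(1, 1, 1))
  ## Q == 0 -> uniform attention: every output frame is the frame-mean of V
  F <- 5
  K2 <- random_batch(c(1, 2, F, 4, 4), 4)
  V2 <- random_batch(c(1, 2, F, 4, 4), 5)
  Q2 <- array(0, dim(K2))
  y2 <- frame_attention(K2, Q2, V2, n_heads = 1)
  mv <- apply(V2, c(1, 2, 4, 5), mean)
  for (f in seq_len(F)) {
    expect_equal(y2[, , f, , ], mv[1, , , ], tolerance = 1e-12)
  }
  ## softmax rows sum to 1 for every head; scores are F x F, never pixels
  K3 <- random_batch(c(2, 4, 6, 5, 7), 6)
  Q3 <- random_batch(c(2, 4, 6, 5, 7), 7)
  r3 <- frame_attention(K3, Q3, K3, n_heads = 2, return_scores = TRUE)
  for (A in r3$scores) {
    expect_identical(dim(A), c(6L, 6L))
    expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-6)
  }
})

test_that("pooled attention matches a brute-force softmax on enumerable tensors", {
  ## B=1, F=2, 1 head, 1x1 frames, 2 channels, hand-set values
  mk <- function(v) array(v, c(1, 2, 2, 1, 1))  # [B, C, F, H, W]
  K <- mk(c(0.3, -1.2, 0.8, 0.4))   # K[c, t]: c fastest
  Q <- mk(c(1.1, 0.2, -0.5, 0.9))
  V <- mk(c(2.0, -1.0, 0.5, 3.0))
  dh <- 2
  Km <- matrix(c(0.3, -1.2, 0.8, 0.4), 2)   # (c, t)
  Qm <- matrix(c(1.1, 0.2, -0.5, 0.9), 2)
  Vm <- matrix(c(2.0, -1.0, 0.5, 3.0), 2)
  S <- t(Qm) %*% Km / sqrt(dh * 1 * 1)
  A <- t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
  O <- Vm %*% t(A)
  got <- frame_attention(K, Q, V, n_heads = 1, return_scores = TRUE)
  expect_equal(got$scores[[1]], A, tolerance = 1e-10)
  expect_equal(as.vector(got$y), as.vector(O), tolerance = 1e-10)
})

test_that("pixelwise attention mode agrees with pooled on 1x1 frames and differs otherwise", {
  ## with a single pixel the two formulations coincide up to the score scale
  K <- random_batch(c(1, 2, 3, 4, 4), 11)
  Q <- random_batch(c(1, 2, 3, 4, 4), 12)
  V <- random_batch(c(1, 2, 3, 4, 4), 13)
  yp <- frame_attention(K, Q, V, 1, mode = "pixelwise")
  expect_identical(dim(yp), dim(V))
  expect_false(isTRUE(all.equal(yp, frame_attention(K, Q, V, 1))))
  K1 <- K[, , , 1, 1, drop = FALSE]; Q1 <- Q[, , , 1, 1, drop = FALSE]
  V1 <- V[, , , 1, 1, drop = FALSE]
  ## pooled scale is 1/sqrt(dh*H*W) = 1/sqrt(dh) at 1x1 = pixelwise scale
  expect_equal(frame_attention(K1, Q1, V1, 1, mode = "pixelwise"),
               frame_attention(K1, Q1, V1, 1, mode = "pooled"),
               tolerance = 1e-12)
})

test_that("cell: residual structure, shape contract, frame equivariance", {
  cfg <- tiny_config()
  model <- randomize_model(init_model(cfg, 2), 9)
  cell <- model$weights$down[[1]]$cells[[1]]
  c <- dim(cell$inp$w)[4]
  x <- random_batch(c(1, c, 4, 8, 8), 3)
  ## zero attention-output and mixer-output convs -> cell == input projection
  zc <- cell
  zc$o$w[] <- 0; zc$o$b[] <- 0; zc$m2$w[] <- 0; zc$m2$b[] <- 0
  got <- cell_forward(x, zc, cfg)
  xi <- faunet:::to_internal(x)
  pr <- faunet:::to_public(faunet:::conv_fw(xi, zc$inp))
  expect_equal(got, pr, tolerance = 1e-12)
  ## shape contract
  y <- cell_forward(x, cell, cfg)
  expect_identical(dim(y), dim(x))
  ## frame-permutation equivariance (no positional encoding)
  perm <- c(2, 4, 1, 3)
  y1 <- cell_forward(x[, , perm, , , drop = FALSE], cell, cfg)
  expect_equal(y1, y[, , perm, , , drop = FALSE], tolerance = 1e-10)
})

test_that("U-net forward: shape preservation and end-to-end equivariance", {
  cfg <- tiny_config()
  model <- randomize_model(init_model(cfg, 1), 21)
  for (sh in list(c(1, 1, 1, 32, 30), c(1, 1, 3, 34, 30),
                  c(2, 1, 8, 64, 64))) {
    x <- random_batch(sh, sum(sh))
    expect_identical(dim(model_forward(model, x)), dim(x))
  }
  x <- random_batch(c(1, 1, 4, 24, 24), 5)
  perm <- c(4, 2, 1, 3)
  y <- model_forward(model, x)
  y2 <- model_forward(model, x[, , perm, , , drop = FALSE])
  expect_equal(y2, y[, , perm, , , drop = FALSE], tolerance = 1e-8)
  ## non-finite input rejected
  xb <- x; xb[1] <- NaN
  expect_error(model_forward(model, xb), "finite")
})

test_that("parameter_count matches an independent layer-by-layer count", {
  ## independent oracle: enumerate every conv (k^2 c_in c_out + c_out) and
  ## every per-channel affine pair, from the architecture definition alone
  count_oracle <- function(C, base, L, cells, k, e) {
    conv <- function(cin, cout) k * k * cin * cout + cout
    cell <- function(c) {
      conv(c, c) +                 # input projection
        2 * c +                    # norm 1 affine
        3 * conv(c, c) +           # K, Q, V
        conv(c, c) +               # attention output projection
        2 * c +                    # norm 2 affine
        conv(c, e * c) + conv(e * c, c)  # mixer
    }
    total <- conv(C, base)                      # pre
    for (l in seq_len(L)) {
      c <- base * 2^(l - 1)
      total <- total + cells * cell(c) + conv(c, 2 * c)
    }
    for (j in seq_len(L)) {
      cj <- base * 2^(L - j + 1)
      total <- total + conv(cj, cj / 2) + conv(cj, cj / 2) +
        cells * cell(cj / 2)
    }
    total + conv(base, C)                       # post
  }
  cfg1 <- model_config(1, 8, 2, 1, 2)
  expect_equal(parameter_count(cfg1), count_oracle(1, 8, 2, 1, 3, 2))
  cfg2 <- model_config(2, 4, 1, 2, 2)
  expect_equal(parameter_count(cfg2), count_oracle(2, 4, 1, 2, 3, 2))
  ## doubling cells_per_level exactly doubles the cell-dependent parameters
  cfg3 <- model_config(1, 8, 2, 2, 2)
  fixed <- count_oracle(1, 8, 2, 0, 3, 2)
  expect_equal(parameter_count(cfg3) - fixed,
                   2 * (parameter_count(cfg1) - fixed))
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- model_config(1, 4, 1, 1, 2)
  model <- randomize_model(init_model(cfg, 3), 17, sd = 0.15)
  v <- faunet:::flatten_params(model$weights)
  xi <- random_batch(c(6, 4, 1, 2, 2), 8)   # internal (H, W, C, F, B)
  tgt <- random_batch(dim(xi), 9)
  lossf <- function(w) {
    mm <- model
    mm$weights <- faunet:::unflatten_params(w, model$weights)
    mean((faunet:::unet_fw(xi, mm)$y - tgt)^2)
  }
  fwd <- faunet:::unet_fw(xi, model, keep = TRUE)
  bw <- faunet:::unet_bw(fwd$cache, 2 * (fwd$y - tgt) / length(xi), model)
  ga <- faunet:::flatten_params(bw$grads)
  idx <- with_seed_test(10, sample(length(v), 40))
  for (i in idx) {
    e <- 1e-5
    vp <- v; vp[i] <- v[i] + e
    vm <- v; vm[i] <- v[i] - e
    gn <- (lossf(vp) - lossf(vm)) / (2 * e)
    expect_equal(ga[i], gn, tolerance = 1e-4)
  }
})

test_that("gradient flows into every parameter tensor (no dead branch)", {
  cfg <- tiny_config()
  model <- randomize_model(init_model(cfg, 4), 23, sd = 0.12)
  xi <- random_batch(c(8, 8, 1, 3, 1), 30)
  tgt <- random_batch(dim(xi), 31)
  fwd <- faunet:::unet_fw(xi, model, keep = TRUE)
  bw <- faunet:::unet_bw(fwd$cache, 2 * (fwd$y - tgt) / length(xi), model)
  check_nonzero <- function(node, path) {
    if (is.list(node)) {
      for (nm in names(node)) check_nonzero(node[[nm]], c(path, nm))
    } else {
      expect_true(any(node != 0),
                  info = paste0("zero gradient tensor at ",
                                paste(path, collapse = "/")))
    }
  }
  check_nonzero(bw$grads, character())
})
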