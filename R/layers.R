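## Differentiable layers on the internal tensor layout (H, W, C, F, B).
## Each layer has a forward producing (value, cache) and a backward taking
## the upstream gradient; gradients are exact (verified against numerical
## differentiation in the test suite).

## ---- 2D convolution (applied identically to every frame) ------------------

conv_fw <- function(x, pm, stride = 1L) {
  d <- dim(x)
  k <- dim(pm$w)[1]
  cout <- dim(pm$w)[4]
  y <- conv2d_fw_cpp(x, d[1], d[2], d[3], d[4] * d[5], pm$w, k, cout,
                     pm$b, as.integer(stride))
  dy <- dim(y)
  dim(y) <- c(dy[1], dy[2], cout, d[4], d[5])
  y
}

conv_bw <- function(x, pm, dy, stride = 1L) {
  d <- dim(x)
  k <- dim(pm$w)[1]
  cout <- dim(pm$w)[4]
  r <- conv2d_bw_cpp(x, d[1], d[2], d[3], d[4] * d[5], pm$w, k, cout,
                     dy, as.integer(stride))
  dim(r$dx) <- d
  dim(r$dw) <- dim(pm$w)
  r
}

conv_params <- function(k, cin, cout, init = c("he", "zero")) {
  init <- match.arg(init)
  w <- if (init == "zero") numeric(k * k * cin * cout) else
    stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin)))
  list(w = array(w, dim = c(k, k, cin, cout)), b = numeric(cout))
}

## ---- instance normalization ----------------------------------------------
## Per (sample, channel) over (F, H, W) jointly, with a per-channel affine.

inorm_fw <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; F <- d[4]; B <- d[5]
  HW <- H * W; M <- HW * F
  s1 <- .colSums(x, HW, C * F * B); dim(s1) <- c(C, F, B)
  s2 <- .colSums(x * x, HW, C * F * B); dim(s2) <- c(C, F, B)
  mu <- apply(s1, c(1, 3), sum) / M                       # C x B
  v <- apply(s2, c(1, 3), sum) / M - mu^2
  inv <- 1 / sqrt(v + eps)                                # C x B
  expand_cb <- function(mcb) {
    rep(as.vector(aperm(array(mcb, dim = c(C, B, F)), c(1, 3, 2))), each = HW)
  }
  xhat <- (x - expand_cb(mu)) * expand_cb(inv)
  gfull <- rep(rep(gamma, each = HW), times = F * B)
  y <- xhat * gfull + rep(rep(beta, each = HW), times = F * B)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, inv = inv, gamma = gamma, dims = d))
}

inorm_bw <- function(cache, dy) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; F <- d[4]; B <- d[5]
  HW <- H * W; M <- HW * F
  xhat <- cache$xhat
  sum_cb <- function(a) {  # (C x B) group sums over (H, W, F)
    s <- .colSums(a, HW, C * F * B); dim(s) <- c(C, F, B)
    apply(s, c(1, 3), sum)
  }
  expand_cb <- function(mcb) {
    rep(as.vector(aperm(array(mcb, dim = c(C, B, F)), c(1, 3, 2))), each = HW)
  }
  sum_c <- function(a) {  # per-channel sums over everything else
    s <- .colSums(a, HW, C * F * B); dim(s) <- c(C, F * B)
    .rowSums(s, C, F * B)
  }
  dgamma <- sum_c(dy * xhat)
  dbeta <- sum_c(dy)
  gfull <- rep(rep(cache$gamma, each = HW), times = F * B)
  dxhat <- dy * gfull
  m1 <- sum_cb(dxhat) / M
  m2 <- sum_cb(dxhat * xhat) / M
  dx <- expand_cb(cache$inv) * (dxhat - expand_cb(m1) - xhat * expand_cb(m2))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- GELU (exact, x * Phi(x)) --------------------------------------------

gelu_fw <- function(x) {
  px <- stats::pnorm(x)
  list(y = x * px, cache = list(x = x, px = px))
}

gelu_bw <- function(cache, dy) {
  dy * (cache$px + cache$x * stats::dnorm(cache$x))
}

## ---- nearest-neighbour 2x spatial upsampling ------------------------------

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , ,
    drop = FALSE]
}

upsample2_bw <- function(dy) {
  d <- dim(dy)
  a <- dy[seq(1, d[1], by = 2), , , , , drop = FALSE] +
    dy[seq(2, d[1], by = 2), , , , , drop = FALSE]
  a[, seq(1, d[2], by = 2), , , , drop = FALSE] +
    a[, seq(2, d[2], by = 2), , , , drop = FALSE]
}

## ---- channel concatenation ------------------------------------------------

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4], da[5]))
  out[, , seq_len(da[3]), , ] <- a
  out[, , da[3] + seq_len(db[3]), , ] <- b
  out
}

split_c <- function(d, c1) {
  list(a = d[, , seq_len(c1), , , drop = FALSE],
       b = d[, , -seq_len(c1), , , drop = FALSE])
}

## ---- reflect padding of H, W to a multiple of 2^levels --------------------

pad_to_multiple <- function(x, m) {
  d <- dim(x)
  ph <- (m - d[1] %% m) %% m
  pw <- (m - d[2] %% m) %% m
  fa_assert(ph < d[1] && pw < d[2],
            "spatial dimensions too small for the number of U-net levels",
            "faunet_config_error")
  idxh <- c(seq_len(d[1]), d[1] - seq_len(ph))
  idxw <- c(seq_len(d[2]), d[2] - seq_len(pw))
  y <- if (ph == 0 && pw == 0) x else x[idxh, idxw, , , , drop = FALSE]
  list(y = y, H0 = d[1], W0 = d[2], ph = ph, pw = pw)
}

pad_crop <- function(y, pad) {
  if (pad$ph == 0 && pad$pw == 0) return(y)
  y[seq_len(pad$H0), seq_len(pad$W0), , , , drop = FALSE]
}

## gradient of crop(pad(x)): embed then fold reflected positions back
pad_bw <- function(dout, pad) {
  if (pad$ph == 0 && pad$pw == 0) return(dout)
  d <- dim(dout)
  dp <- array(0, dim = c(pad$H0 + pad$ph, pad$W0 + pad$pw, d[3], d[4], d[5]))
  dp[seq_len(pad$H0), seq_len(pad$W0), , , ] <- dout
  dp
}

pad_fold <- function(dxp, pad) {
  H0 <- pad$H0; W0 <- pad$W0
  for (j in seq_len(pad$ph)) {
    dxp[H0 - j, , , , ] <- dxp[H0 - j, , , , ] + dxp[H0 + j, , , , ]
  }
  for (j in seq_len(pad$pw)) {
    dxp[, W0 - j, , , ] <- dxp[, W0 - j, , , ] + dxp[, W0 + j, , , ]
  }
  dxp[seq_len(H0), seq_len(W0), , , , drop = FALSE]
}
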