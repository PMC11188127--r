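## Image-quality metrics: PSNR and volumetric SSIM with a separable 3D
## Gaussian window.  The SSIM core also exposes its analytic gradient,
## which the training loss uses; filtering is done with per-axis band
## matrices (symmetric edge padding), so the adjoint needed by the
## gradient is just the transposed matrix.

gauss_kernel1d <- function(sigma, radius) {
  if (radius == 0) return(1)
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k / sum(k)
}

## n x n filtering operator along one axis with symmetric (mirror) padding
band_matrix <- function(n, kern) {
  r <- (length(kern) - 1) / 2
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in -r:r) {
      p <- i + j
      if (p < 1) p <- 1 - p          # symmetric: ..., 2, 1 | 1, 2, ...
      if (p > n) p <- 2 * n + 1 - p
      M[i, p] <- M[i, p] + kern[j + r + 1]
    }
  }
  M
}

filter_axis <- function(vol, M, axis) {
  d <- dim(vol)
  if (axis == 1) {
    out <- M %*% matrix(vol, d[1])
    dim(out) <- d
    return(out)
  }
  perm <- seq_along(d)
  perm[c(1, axis)] <- perm[c(axis, 1)]
  v <- aperm(vol, perm)
  out <- M %*% matrix(v, d[axis])
  dim(out) <- dim(v)
  aperm(out, perm)
}

filter_sep <- function(vol, mats) {
  for (ax in seq_along(mats)) {
    if (!is.null(mats[[ax]])) vol <- filter_axis(vol, mats[[ax]], ax)
  }
  vol
}

ssim_mats <- function(dims, window, sigma = 1.5, transpose = FALSE) {
  lapply(dims, function(n) {
    w <- min(window, if (n %% 2 == 1) n else n - 1)
    if (w < 1) w <- 1
    r <- (w - 1) / 2
    M <- band_matrix(n, gauss_kernel1d(sigma, r))
    if (transpose) t(M) else M
  })
}

## Volumetric SSIM on two equally-shaped 3-d arrays; optionally with the
## gradient of the mean score w.r.t. x.
ssim_vol <- function(x, y, window = 11, k1 = 0.01, k2 = 0.03,
                     data_range = 1, grad = FALSE) {
  d <- dim(x)
  G <- ssim_mats(d, window)
  C1 <- (k1 * data_range)^2
  C2 <- (k2 * data_range)^2
  mux <- filter_sep(x, G); muy <- filter_sep(y, G)
  Sxx <- filter_sep(x * x, G); Syy <- filter_sep(y * y, G)
  Sxy <- filter_sep(x * y, G)
  sx2 <- Sxx - mux^2; sy2 <- Syy - muy^2; sxy <- Sxy - mux * muy
  A1 <- 2 * mux * muy + C1; B1 <- mux^2 + muy^2 + C1
  A2 <- 2 * sxy + C2; B2 <- sx2 + sy2 + C2
  map <- (A1 * A2) / (B1 * B2)
  score <- mean(map)
  if (!grad) return(list(score = score))
  nvox <- length(x)
  ## partials of map w.r.t. (mux, Sxx, Sxy); mu enters sigma terms too
  d_Sxx <- -(A1 * A2) / (B1 * B2^2)
  d_Sxy <- (A1 / B1) * (2 / B2)
  d_mux <- (2 * muy * B1 - 2 * mux * A1) / B1^2 * (A2 / B2) +
    (A1 / B1) * ((-2 * muy) * B2 - A2 * (-2 * mux)) / B2^2
  Gt <- ssim_mats(d, window, transpose = TRUE)
  dx <- filter_sep(d_mux, Gt) + 2 * x * filter_sep(d_Sxx, Gt) +
    y * filter_sep(d_Sxy, Gt)
  list(score = score, dx = dx / nvox)
}

.metric_array <- function(x) {
  if (inherits(x, "faunet_stack")) return(x$voxels)
  fa_assert(is.numeric(x) && !is.null(dim(x)), "expected a stack or array")
  x
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(data_range^2 / MSE)` in dB; `Inf` when the images are equal.
#'
#' @param x,ref [image_stack]s or arrays of identical shape.
#' @param data_range intensity range of the data (1 for normalized stacks).
#' @export
psnr <- function(x, ref, data_range = 1) {
  a <- .metric_array(x); b <- .metric_array(ref)
  fa_assert(identical(dim(a), dim(b)), "psnr: shape mismatch")
  fa_assert(data_range > 0, "data_range must be > 0")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Volumetric structural similarity (SSIM3D)
#'
#' Standard SSIM with a 3D Gaussian window (sigma 1.5) spanning
#' (frames, height, width), averaged over all voxels and channels.  The
#' window is clipped per axis to the largest odd size not exceeding that
#' axis, so short frame axes are handled.
#'
#' @param x,ref [image_stack]s or `[C, F, H, W]` arrays of identical shape.
#' @param window odd window size (per axis, before clipping).
#' @param k1,k2 SSIM stabilization constants.
#' @param data_range intensity range.
#' @return score in `[-1, 1]`; 1 iff the inputs are identical.
#' @export
ssim3d <- function(x, ref, window = 11, k1 = 0.01, k2 = 0.03,
                   data_range = 1) {
  fa_assert(window %% 2 == 1, "ssim3d window must be odd",
            "faunet_config_error")
  a <- .metric_array(x); b <- .metric_array(ref)
  fa_assert(identical(dim(a), dim(b)), "ssim3d: shape mismatch")
  C <- dim(a)[1]
  scores <- vapply(seq_len(C), function(c) {
    va <- a[c, , , , drop = FALSE]; dim(va) <- dim(a)[2:4]
    vb <- b[c, , , , drop = FALSE]; dim(vb) <- dim(b)[2:4]
    ssim_vol(va, vb, window, k1, k2, data_range)$score
  }, numeric(1))
  mean(scores)
}

## ---- training loss --------------------------------------------------------

## Internal-layout loss: weighted MSE + (1 - mean SSIM3D), with gradient.
loss_int <- function(pred, target, weights, ssim_window = 7, grad = FALSE) {
  fa_assert(identical(dim(pred), dim(target)), "loss: shape mismatch")
  w_mse <- weights[["mse"]]; w_ssim <- weights[["ssim"]]
  d <- dim(pred)
  n <- length(pred)
  diff <- pred - target
  mse <- mean(diff^2)
  val <- w_mse * mse
  dx <- if (grad) w_mse * 2 * diff / n else NULL
  if (w_ssim > 0) {
    C <- d[3]; B <- d[5]
    acc <- 0
    for (b in seq_len(B)) {
      for (c in seq_len(C)) {
        vx <- pred[, , c, , b, drop = FALSE]; dim(vx) <- d[c(1, 2, 4)]
        vy <- target[, , c, , b, drop = FALSE]; dim(vy) <- d[c(1, 2, 4)]
        r <- ssim_vol(vx, vy, window = ssim_window, grad = grad)
        acc <- acc + r$score
        if (grad) dx[, , c, , b] <- dx[, , c, , b] -
            w_ssim * r$dx / (C * B)
      }
    }
    val <- val + w_ssim * (1 - acc / (C * B))
  }
  list(value = val, dx = dx)
}

#' Training loss: weighted MSE plus structural dissimilarity
#'
#' `weights["mse"] * MSE + weights["ssim"] * (1 - mean SSIM3D)`.
#' Non-negative, and zero iff `pred == target` when both weights are
#' positive.
#'
#' @param pred,target 5-d arrays `[B, C, F, H, W]` of identical shape.
#' @param weights named vector with elements `mse` and `ssim`, both
#'   `>= 0`, not both zero.
#' @param ssim_window window for the SSIM term.
#' @return scalar loss.
#' @export
denoise_loss <- function(pred, target, weights = c(mse = 1, ssim = 0.1),
                         ssim_window = 7) {
  fa_assert(all(weights[c("mse", "ssim")] >= 0) &&
              sum(weights[c("mse", "ssim")]) > 0,
            "loss weights must be >= 0 and not both zero",
            "faunet_config_error")
  loss_int(to_internal(pred), to_internal(target), weights,
           ssim_window, grad = FALSE)$value
}
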