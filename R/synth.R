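## Synthetic fluorescence phantoms and a photon-limited noise model.
##
## Structure families stand in for the organelle / tissue structures of
## real acquisitions: drifting filament curves (backbone domain), jittering
## Gaussian blobs (fine-tune domain) and static branching tube networks.
## Frames drift slowly rather than being independent, so cross-frame
## attention has exploitable signal coherence.  Noise is the standard
## fluorescence camera model: Poisson shot noise at a configurable photon
## level plus additive Gaussian read noise, with optional repeat averaging
## emulating line/frame averaging.

#' Phantom specification
#'
#' @param kind `"filaments"`, `"blobs"` or `"tubes"`.
#' @param shape `(F, H, W)` frames and pixels.
#' @param density number of structures.
#' @param intensity_range per-structure peak intensity range, inside
#'   `(0, 1]`.
#' @param psf_sigma Gaussian PSF width in pixels (0 disables blurring).
#' @param background constant background level in `[0, 1)`.
#' @param seed integer; generation is deterministic given the seed.
#' @export
phantom_spec <- function(kind = c("filaments", "blobs", "tubes"),
                         shape = c(4, 48, 48), density = 6,
                         intensity_range = c(0.4, 0.9), psf_sigma = 1,
                         background = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  chk <- function(cond, msg) fa_assert(cond, msg, "faunet_config_error")
  chk(length(shape) == 3 && all(shape >= 1), "shape must be (F, H, W) >= 1")
  chk(shape[2] * shape[3] > 0, "zero-area phantom shape")
  chk(intensity_range[1] < intensity_range[2] && intensity_range[2] <= 1 &&
        intensity_range[1] > 0, "need 0 < lo < hi <= 1 intensity range")
  chk(psf_sigma >= 0, "psf_sigma must be >= 0")
  chk(density >= 1, "density must be >= 1")
  chk(background >= 0 && background < 1, "background must be in [0, 1)")
  structure(list(kind = kind, shape = as.integer(shape),
                 density = as.integer(density),
                 intensity_range = intensity_range, psf_sigma = psf_sigma,
                 background = background, seed = as.integer(seed)),
            class = "faunet_phantom_spec")
}

## deposit anti-aliased points (fractional coords) into an H x W frame
.deposit_points <- function(H, W, py, px) {
  img <- numeric(H * W)
  iy <- floor(py); ix <- floor(px)
  fy <- py - iy; fx <- px - ix
  for (dy in 0:1) {
    for (dx in 0:1) {
      yy <- iy + dy; xx <- ix + dx
      wgt <- (if (dy == 0) 1 - fy else fy) * (if (dx == 0) 1 - fx else fx)
      ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W & wgt > 0
      if (!any(ok)) next
      idx <- yy[ok] + (xx[ok] - 1) * H
      s <- rowsum(wgt[ok], idx)
      img[as.integer(rownames(s))] <- img[as.integer(rownames(s))] + s[, 1]
    }
  }
  matrix(img, H, W)
}

.curve_points <- function(y0, x0, theta0, len, wiggle, step = 0.4) {
  n <- max(2L, ceiling(len / step))
  th <- theta0 + cumsum(c(0, stats::rnorm(n - 1, sd = wiggle)))
  py <- y0 + cumsum(c(0, sin(th[-1]) * step))
  px <- x0 + cumsum(c(0, cos(th[-1]) * step))
  cbind(py, px)
}

#' Generate a clean phantom stack
#'
#' Filaments are smoothed random-walk curves rasterized with sub-pixel
#' anti-aliasing that drift slowly across frames; blobs are Gaussian spots
#' with per-frame center jitter; tubes are branching curvilinear networks
#' constant across frames.  The structure image is blurred by a Gaussian
#' PSF, the background is added and the result clipped to `[0, 1]`.
#'
#' @param spec a [phantom_spec].
#' @return an [image_stack] `[1, F, H, W]` with values in `[0, 1]`.
#' @export
make_clean_stack <- function(spec) {
  fa_assert(inherits(spec, "faunet_phantom_spec"), "expected a phantom_spec",
            "faunet_config_error")
  F <- spec$shape[1]; H <- spec$shape[2]; W <- spec$shape[3]
  lo <- spec$intensity_range[1]; hi <- spec$intensity_range[2]
  vol <- with_seed(spec$seed, {
    v <- array(0, dim = c(H, W, F))
    if (spec$kind == "blobs") {
      cy <- stats::runif(spec$density, 0.15 * H, 0.85 * H)
      cx <- stats::runif(spec$density, 0.15 * W, 0.85 * W)
      sg <- stats::runif(spec$density, 1.5, 3)
      amp <- stats::runif(spec$density, lo, hi)
      for (f in seq_len(F)) {
        jy <- cy + stats::rnorm(spec$density, sd = 0.4)
        jx <- cx + stats::rnorm(spec$density, sd = 0.4)
        img <- matrix(0, H, W)
        for (i in seq_len(spec$density)) {
          gy <- exp(-((seq_len(H) - jy[i])^2) / (2 * sg[i]^2))
          gx <- exp(-((seq_len(W) - jx[i])^2) / (2 * sg[i]^2))
          img <- img + amp[i] * outer(gy, gx)
        }
        v[, , f] <- img
      }
    } else if (spec$kind == "filaments") {
      for (i in seq_len(spec$density)) {
        pts <- .curve_points(stats::runif(1, 0.15 * H, 0.85 * H),
                             stats::runif(1, 0.15 * W, 0.85 * W),
                             stats::runif(1, 0, 2 * pi),
                             stats::runif(1, 0.5, 1.1) * min(H, W),
                             wiggle = 0.12)
        amp <- stats::runif(1, lo, hi)
        vdrift <- stats::rnorm(2, sd = 0.5)   # px per frame
        for (f in seq_len(F)) {
          off <- vdrift * (f - 1)
          mask <- .deposit_points(H, W, pts[, 1] + off[1], pts[, 2] + off[2])
          v[, , f] <- v[, , f] + amp * pmin(mask, 1)
        }
      }
    } else {  # tubes: branching network, constant across frames
      segs <- list(list(y = stats::runif(1, 0.2 * H, 0.8 * H),
                        x = stats::runif(1, 0.2 * W, 0.8 * W),
                        th = stats::runif(1, 0, 2 * pi)))
      img <- matrix(0, H, W)
      amp <- stats::runif(1, lo, hi)
      made <- 0
      while (length(segs) > 0 && made < spec$density) {
        s <- segs[[1]]; segs[[1]] <- NULL
        pts <- .curve_points(s$y, s$x, s$th,
                             stats::runif(1, 0.3, 0.7) * min(H, W),
                             wiggle = 0.08)
        img <- img + pmin(.deposit_points(H, W, pts[, 1], pts[, 2]), 1)
        made <- made + 1
        nb <- stats::rpois(1, 1.2)
        if (nb > 0) {
          at <- sample(nrow(pts), min(nb, nrow(pts)))
          for (a in at) {
            segs[[length(segs) + 1L]] <-
              list(y = pts[a, 1], x = pts[a, 2],
                   th = s$th + stats::runif(1, -1, 1) * 0.9)
          }
        }
      }
      img <- amp * pmin(img, 1)
      for (f in seq_len(F)) v[, , f] <- img
    }
    v
  })
  if (spec$psf_sigma > 0) {
    r <- ceiling(3 * spec$psf_sigma)
    kern <- gauss_kernel1d(spec$psf_sigma, r)
    Mh <- band_matrix(H, kern); Mw <- band_matrix(W, kern)
    for (f in seq_len(F)) {
      vol[, , f] <- Mh %*% vol[, , f] %*% t(Mw)
    }
  }
  vol <- pmin(pmax(vol + spec$background, 0), 1)
  ## aperm gives (F, H, W); prepend the singleton channel axis
  vox <- array(aperm(vol, c(3, 1, 2)), dim = c(1, F, H, W))
  image_stack(vox)
}

#' Photon-noise model parameters
#'
#' @param photon_level expected photons at unit intensity (alpha).
#' @param read_sigma additive Gaussian read-noise std, in photon units.
#' @param n_average number of independent repeats averaged (line/frame
#'   averaging).
#' @export
noise_params <- function(photon_level, read_sigma = 0, n_average = 1L) {
  fa_assert(photon_level > 0, "photon_level must be > 0",
            "faunet_config_error")
  fa_assert(read_sigma >= 0, "read_sigma must be >= 0",
            "faunet_config_error")
  fa_assert(n_average >= 1, "n_average must be >= 1", "faunet_config_error")
  structure(list(photon_level = photon_level, read_sigma = read_sigma,
                 n_average = as.integer(n_average)),
            class = "faunet_noise_params")
}

#' Degrade a clean stack with Poisson-Gaussian noise
#'
#' For each of `n_average` independent repeats, every voxel draws
#' `Poisson(alpha * clean) + Normal(0, read_sigma^2)`; the repeats are
#' averaged and divided by `alpha`, returning to the (approximate)
#' `[0, 1]` intensity scale.
#'
#' @param clean an [image_stack] with values in `[0, 1]`.
#' @param noise a [noise_params].
#' @param seed integer seed; deterministic.
#' @export
degrade <- function(clean, noise, seed = 1L) {
  clean <- as_image_stack(clean)
  fa_assert(inherits(noise, "faunet_noise_params"), "expected noise_params",
            "faunet_config_error")
  fa_assert(min(clean$voxels) >= 0 && max(clean$voxels) <= 1,
            "clean stack must be in [0, 1]")
  a <- noise$photon_level
  lam <- a * as.vector(clean$voxels)
  n <- length(lam)
  out <- with_seed(seed, {
    acc <- numeric(n)
    for (r in seq_len(noise$n_average)) {
      rep_ <- stats::rpois(n, lam)
      if (noise$read_sigma > 0)
        rep_ <- rep_ + stats::rnorm(n, sd = noise$read_sigma)
      acc <- acc + rep_
    }
    acc / (noise$n_average * a)
  })
  st <- clean
  st$voxels <- array(out, dim = dim(clean$voxels))
  st
}

#' Generate a paired low/high SNR dataset on disk
#'
#' Each pair shares one clean phantom degraded twice: the low-SNR member
#' as a single (or few-shot) acquisition and the high-SNR member with a
#' large repeat average, mirroring single-shot vs line-averaged real
#' acquisitions.  Stacks are written as float32 TIFF with a TSV manifest.
#'
#' @param n_pairs number of pairs.
#' @param spec_template a [phantom_spec]; each pair uses a seed derived
#'   from `seed` and the pair index.
#' @param low_noise,high_noise [noise_params]; `low_noise` must be
#'   strictly noisier (`photon_level * n_average` smaller).
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param split_counts named integer vector `c(train=, val=, test=)`;
#'   default assigns roughly 70/15/15 in index order.
#' @return the [manifest] (also saved as `manifest.tsv` in `out_dir`).
#' @export
make_pair_dataset <- function(n_pairs, spec_template, low_noise, high_noise,
                              out_dir, seed = 1L, split_counts = NULL) {
  fa_assert(inherits(spec_template, "faunet_phantom_spec"),
            "expected a phantom_spec", "faunet_config_error")
  fa_assert(low_noise$photon_level * low_noise$n_average <
              high_noise$photon_level * high_noise$n_average,
            "low_noise must be strictly noisier than high_noise",
            "faunet_config_error")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) fa_stop(paste0("cannot create output directory: ", out_dir),
                     "faunet_io_error")
  }
  if (is.null(split_counts)) {
    n_train <- max(1L, round(0.7 * n_pairs))
    n_val <- max(0L, round(0.15 * n_pairs))
    split_counts <- c(train = n_train, val = n_val,
                      test = n_pairs - n_train - n_val)
  }
  fa_assert(sum(split_counts) == n_pairs,
            "split_counts must sum to n_pairs", "faunet_config_error")
  splits <- rep(c("train", "val", "test"),
                times = split_counts[c("train", "val", "test")])
  entries <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    spec_i <- spec_template
    spec_i$seed <- derive_seed(seed, i, 1L)
    clean <- make_clean_stack(spec_i)
    low <- degrade(clean, low_noise, derive_seed(seed, i, 2L))
    high <- degrade(clean, high_noise, derive_seed(seed, i, 3L))
    pid <- sprintf("%s_%03d", spec_template$kind, i)
    lp <- sprintf("%s_low.tif", pid); hp <- sprintf("%s_high.tif", pid)
    write_stack(low, file.path(out_dir, lp), "float32")
    write_stack(high, file.path(out_dir, hp), "float32")
    entries[[i]] <- data.frame(pair_id = pid, low_path = lp, high_path = hp,
                               split = splits[i], tags = spec_template$kind,
                               stringsAsFactors = FALSE)
  }
  m <- manifest(do.call(rbind, entries), dir = out_dir)
  save_manifest(m, file.path(out_dir, "manifest.tsv"))
  m
}

#' Generate a repetition-average series
#'
#' N independent single-shot degradations of one clean stack; member n is
#' the running mean of repeats 1..n, so the series emulates acquiring 64
#' repetitions of one field-of-view and averaging the first n.  Member N
#' serves as the acquisition-style ground truth; the clean stack is kept
#' for oracle metrics.
#'
#' @param spec a [phantom_spec].
#' @param noise a [noise_params]; its `n_average` is ignored (repeats are
#'   single shots).
#' @param N series length (>= 2), conventionally 64.
#' @param seed master seed.
#' @return a `faunet_avg_series` with `members` (list of stacks),
#'   `clean`, and `ground_truth_index = N`.
#' @export
make_average_series <- function(spec, noise, N = 64L, seed = 1L) {
  fa_assert(N >= 2, "N must be >= 2", "faunet_config_error")
  clean <- make_clean_stack(spec)
  shot <- noise_params(noise$photon_level, noise$read_sigma, 1L)
  members <- vector("list", N)
  acc <- array(0, dim = dim(clean$voxels))
  for (n in seq_len(N)) {
    rep_ <- degrade(clean, shot, derive_seed(seed, n))
    acc <- acc + rep_$voxels
    st <- clean
    st$voxels <- acc / n
    members[[n]] <- st
  }
  structure(list(members = members, clean = clean,
                 ground_truth_index = as.integer(N), noise = noise,
                 seed = as.integer(seed)),
            class = "faunet_avg_series")
}
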