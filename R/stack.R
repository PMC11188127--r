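## ImageStack, StackPair, percentile normalization.

#' Construct an ImageStack
#'
#' The package's basic container: one sample's voxels as a 4-axis array
#' `[C, F, H, W]` — color/stain channels, frames (Z depth or T time,
#' treated interchangeably), then pixel rows and columns.
#'
#' @param voxels 4-d finite numeric array `[C, F, H, W]`.
#' @param axis_label what the frame axis means, `"Z"` or `"T"`.
#' @param dtype_origin sample type of the source data
#'   (`"uint8"`, `"uint16"`, `"float32"`).
#' @param pixel_size optional pixel pitch in microns.
#' @return an object of class `faunet_stack`.
#' @export
image_stack <- function(voxels, axis_label = c("Z", "T"),
                        dtype_origin = c("float32", "uint8", "uint16"),
                        pixel_size = NULL) {
  axis_label <- match.arg(axis_label)
  dtype_origin <- match.arg(dtype_origin)
  fa_assert(is.numeric(voxels) && length(dim(voxels)) == 4,
            "voxels must be a 4-d numeric array [C, F, H, W]")
  fa_assert(all(dim(voxels) >= 1), "all stack dimensions must be >= 1")
  fa_assert(all(is.finite(voxels)), "stack voxels must be finite")
  structure(list(voxels = voxels, axis_label = axis_label,
                 dtype_origin = dtype_origin, pixel_size = pixel_size),
            class = "faunet_stack")
}

as_image_stack <- function(x) {
  if (inherits(x, "faunet_stack")) return(x)
  if (is.numeric(x) && !is.null(dim(x)) && length(dim(x)) == 4)
    return(image_stack(x))
  fa_stop("expected an image_stack or a 4-d [C, F, H, W] array")
}

#' @export
print.faunet_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<faunet_stack> [C=%d, %s=%d, H=%d, W=%d]  range [%.4g, %.4g]  (%s)\n",
    d[1], x$axis_label, d[2], d[3], d[4],
    min(x$voxels), max(x$voxels), x$dtype_origin))
  invisible(x)
}

#' @export
dim.faunet_stack <- function(x) dim(x$voxels)

#' Construct a matched low/high SNR pair
#'
#' Members must be pixel-registered: identical shape and frame-axis label.
#'
#' @param low,high [image_stack]s.
#' @param pair_id identifier string.
#' @export
stack_pair <- function(low, high, pair_id = "pair") {
  low <- as_image_stack(low); high <- as_image_stack(high)
  fa_assert(identical(dim(low$voxels), dim(high$voxels)),
            "pair members must have identical shapes")
  fa_assert(identical(low$axis_label, high$axis_label),
            "pair members must share the frame-axis label")
  structure(list(low = low, high = high, pair_id = as.character(pair_id)),
            class = "faunet_pair")
}

#' Normalization parameters
#'
#' The affine map fitted by [normalize_stack]; kept so the map can be
#' inverted after inference.
#'
#' @param p_low_value,p_high_value intensity values mapped to 0 and 1.
#' @param p_low_q,p_high_q the percentiles they came from.
#' @export
norm_params <- function(p_low_value, p_high_value, p_low_q = 0.5,
                        p_high_q = 99.8) {
  fa_assert(p_high_value > p_low_value,
            "degenerate normalization: high percentile equals low percentile")
  structure(list(p_low_value = p_low_value, p_high_value = p_high_value,
                 p_low_q = p_low_q, p_high_q = p_high_q),
            class = "faunet_norm_params")
}

#' Percentile-normalize a stack to [0, 1]
#'
#' Values are mapped by `(x - v_low) / (v_high - v_low)` where `v_low`,
#' `v_high` are the stack's `p_low_q` / `p_high_q` percentiles, then
#' clipped to `[0, 1]` (unless `clip = FALSE`, used at inference so the
#' affine map stays exactly invertible).  Percentile defaults are robust
#' to the hot pixels typical of photon-limited acquisitions.
#'
#' @param stack an [image_stack].
#' @param p_low_q,p_high_q percentiles in `[0, 100]`, low < high.
#' @param clip clip the mapped values into `[0, 1]`?
#' @param params optional pre-fitted [norm_params] to apply instead of
#'   fitting from this stack (used to share the low-SNR member's statistics
#'   across a pair).
#' @return `list(stack = normalized stack, params = norm_params)`.
#' @export
normalize_stack <- function(stack, p_low_q = 0.5, p_high_q = 99.8,
                            clip = TRUE, params = NULL) {
  stack <- as_image_stack(stack)
  if (is.null(params)) {
    fa_assert(p_low_q >= 0 && p_low_q < p_high_q && p_high_q <= 100,
              "need 0 <= p_low_q < p_high_q <= 100", "faunet_config_error")
    qs <- stats::quantile(stack$voxels, probs = c(p_low_q, p_high_q) / 100,
                          names = FALSE)
    if (qs[2] <= qs[1])
      fa_stop("degenerate input: normalization percentiles coincide (constant stack?)")
    params <- norm_params(qs[1], qs[2], p_low_q, p_high_q)
  }
  v <- (stack$voxels - params$p_low_value) /
    (params$p_high_value - params$p_low_value)
  if (clip) v <- pmin(pmax(v, 0), 1)
  out <- stack
  out$voxels <- v
  list(stack = out, params = params)
}

#' Invert a percentile normalization
#'
#' The exact affine inverse of [normalize_stack]; clipping is not undone.
#'
#' @param stack normalized [image_stack].
#' @param params the [norm_params] returned by [normalize_stack].
#' @export
denormalize_stack <- function(stack, params) {
  stack <- as_image_stack(stack)
  fa_assert(inherits(params, "faunet_norm_params"),
            "params must be faunet_norm_params")
  out <- stack
  out$voxels <- stack$voxels *
    (params$p_high_value - params$p_low_value) + params$p_low_value
  out
}

#' Normalize both members of a pair from the low-SNR member's statistics
#'
#' Network input statistics at inference (where no high-SNR image exists)
#' must match training, so the percentile window is always fitted on the
#' low-SNR member and applied to both.
#'
#' @param pair a [stack_pair].
#' @inheritParams normalize_stack
#' @return `list(pair = normalized pair, params = norm_params)`.
#' @export
normalize_pair <- function(pair, p_low_q = 0.5, p_high_q = 99.8) {
  fa_assert(inherits(pair, "faunet_pair"), "expected a stack_pair")
  nl <- normalize_stack(pair$low, p_low_q, p_high_q)
  nh <- normalize_stack(pair$high, params = nl$params)
  list(pair = stack_pair(nl$stack, nh$stack, pair$pair_id),
       params = nl$params)
}
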