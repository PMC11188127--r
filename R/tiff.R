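## Minimal baseline TIFF codec (no R TIFF package is available in this
## stack, so the subset needed for microscopy stacks is implemented here):
## uncompressed grayscale or chunky multi-sample pages, uint8/uint16/float32,
## little- or big-endian read, little-endian write, one strip per page.

.le2 <- function(x) as.raw(c(x %% 256, x %/% 256))
.le4 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.rd_int <- function(bytes, endian) {
  v <- as.numeric(bytes)
  if (endian == "big") v <- rev(v)
  sum(v * 256^(seq_along(v) - 1))
}

## Read one IFD entry's value vector (numeric) given whole-file raw.
.tiff_entry_value <- function(raw, entry_off, endian) {
  ## entry_off is the 0-based file offset of the 12-byte entry
  type <- .rd_int(raw[entry_off + 3:4], endian)
  count <- .rd_int(raw[entry_off + 5:8], endian)
  size <- switch(as.character(type), "1" = 1L, "2" = 1L, "3" = 2L,
                 "4" = 4L, "11" = 4L, NA_integer_)
  if (is.na(size)) return(NULL)
  nbytes <- size * count
  if (nbytes <= 4) {
    off <- entry_off + 8
  } else {
    off <- .rd_int(raw[entry_off + 9:12], endian)
  }
  bytes <- raw[(off + 1):(off + nbytes)]
  if (type == 11L) {  # FLOAT
    return(readBin(bytes, "double", n = count, size = 4L, endian = endian))
  }
  vapply(seq_len(count), function(i) {
    .rd_int(bytes[((i - 1) * size + 1):(i * size)], endian)
  }, numeric(1))
}

.tiff_parse <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) fa_stop(paste0("not a TIFF file: ", path),
                               "faunet_io_error")
  magic <- rawToChar(raw[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    fa_stop(paste0("not a TIFF file (bad byte-order mark): ", path),
            "faunet_io_error")
  if (.rd_int(raw[3:4], endian) != 42)
    fa_stop(paste0("not a TIFF file (bad magic): ", path), "faunet_io_error")
  ifd_off <- .rd_int(raw[5:8], endian)
  pages <- list()
  while (ifd_off != 0) {
    n_ent <- .rd_int(raw[ifd_off + 1:2], endian)
    tags <- list()
    for (i in seq_len(n_ent)) {
      eoff <- ifd_off + 2 + (i - 1) * 12   # 0-based entry offset
      tag <- .rd_int(raw[eoff + 1:2], endian)
      tags[[as.character(tag)]] <- .tiff_entry_value(raw, eoff, endian)
    }
    pages[[length(pages) + 1L]] <- tags
    ifd_off <- .rd_int(raw[ifd_off + 2 + n_ent * 12 + 1:4], endian)
  }
  list(raw = raw, endian = endian, pages = pages)
}

.tiff_decode_page <- function(parsed, tags, path) {
  g <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v
  }
  W <- g(256); H <- g(257)
  if (is.null(W) || is.null(H))
    fa_stop(paste0("TIFF page missing dimensions: ", path), "faunet_io_error")
  comp <- g(259, 1)
  if (comp != 1)
    fa_stop(paste0("unsupported TIFF compression (", comp, "): ", path),
            "faunet_io_error")
  spp <- g(277, 1)
  bits <- g(258, 1)
  if (length(bits) == 1) bits <- rep(bits, spp)
  fmt <- g(339, rep(1, spp))
  if (length(fmt) == 1) fmt <- rep(fmt, spp)
  planar <- g(284, 1)
  if (planar != 1 && spp > 1)
    fa_stop(paste0("unsupported planar TIFF layout: ", path), "faunet_io_error")
  offs <- g(273); cnts <- g(279)
  if (is.null(offs))
    fa_stop(paste0("TIFF page missing strip offsets: ", path), "faunet_io_error")
  if (is.null(cnts)) cnts <- W * H * spp * bits[1] / 8
  bytes <- do.call(c, lapply(seq_along(offs), function(i) {
    parsed$raw[(offs[i] + 1):(offs[i] + cnts[i])]
  }))
  n <- W * H * spp
  b <- bits[1]
  if (any(bits != b) || any(fmt != fmt[1]))
    fa_stop(paste0("mixed sample formats in TIFF page: ", path),
            "faunet_io_error")
  v <- if (fmt[1] == 3 && b == 32) {
    readBin(bytes, "double", n = n, size = 4L, endian = parsed$endian)
  } else if (fmt[1] %in% c(1, 4) && b == 16) {
    readBin(bytes, "integer", n = n, size = 2L, signed = FALSE,
            endian = parsed$endian)
  } else if (fmt[1] %in% c(1, 4) && b == 8) {
    as.integer(bytes)
  } else {
    fa_stop(sprintf("unsupported TIFF sample type (%d bits, format %d): %s",
                    b, fmt[1], path), "faunet_io_error")
  }
  dtype <- if (fmt[1] == 3) "float32" else if (b == 16) "uint16" else "uint8"
  ## chunky order is (sample, column, row)
  page <- aperm(array(as.numeric(v), dim = c(spp, W, H)), c(1, 3, 2))
  list(page = page, dtype = dtype, H = H, W = W, C = spp)
}

#' Read a multi-page TIFF into an ImageStack
#'
#' Pages map to the frame axis (Z or T); multi-sample (chunky) pages map to
#' channels; grayscale pages give one channel.  Values are returned as
#' doubles exactly as stored, without rescaling, and the on-disk sample
#' type is recorded in `dtype_origin`.
#'
#' @param path path to a single- or multi-page uncompressed TIFF.
#' @param axis_label what the frame axis means, `"Z"` or `"T"`.
#' @return an [image_stack] with voxels `[C, F, H, W]`.
#' @export
read_stack <- function(path, axis_label = c("Z", "T")) {
  axis_label <- match.arg(axis_label)
  if (!file.exists(path))
    fa_stop(paste0("cannot read TIFF, no such file: ", path), "faunet_io_error")
  parsed <- .tiff_parse(path)
  if (length(parsed$pages) == 0)
    fa_stop(paste0("TIFF has no pages: ", path), "faunet_io_error")
  decoded <- lapply(parsed$pages, function(tg)
    .tiff_decode_page(parsed, tg, path))
  H <- decoded[[1]]$H; W <- decoded[[1]]$W; C <- decoded[[1]]$C
  for (d in decoded) {
    if (d$H != H || d$W != W || d$C != C)
      fa_stop(paste0("TIFF pages have inconsistent dimensions: ", path),
              "faunet_io_error")
  }
  F <- length(decoded)
  vox <- array(0, dim = c(C, F, H, W))
  for (f in seq_len(F)) vox[, f, , ] <- decoded[[f]]$page
  image_stack(vox, axis_label = axis_label, dtype_origin = decoded[[1]]$dtype)
}

.tiff_pack_entry <- function(tag, type, values, data_env) {
  size <- if (type == 3L) 2L else 4L
  count <- length(values)
  pack1 <- if (type == 3L) .le2 else .le4
  vb <- do.call(c, lapply(values, pack1))
  if (length(vb) <= 4) {
    val4 <- c(vb, as.raw(rep(0, 4 - length(vb))))
  } else {
    if (length(vb) %% 2 == 1) vb <- c(vb, as.raw(0))
    data_env$overflow[[length(data_env$overflow) + 1L]] <-
      list(tag = tag, bytes = vb)
    val4 <- .le4(0)  # patched once the overflow offset is known
  }
  c(.le2(tag), .le2(type), .le4(count), val4)
}

#' Write an ImageStack as a multi-page TIFF
#'
#' One page per frame; channels are interleaved per pixel (chunky) so the
#' file round-trips through [read_stack].  `uint16` scales `[0, 1]` to
#' `0..65535`; out-of-range values are an error, never clipped silently.
#'
#' @param stack an [image_stack].
#' @param path output path.
#' @param dtype `"float32"` (lossless) or `"uint16"`.
#' @export
write_stack <- function(stack, path, dtype = c("float32", "uint16")) {
  dtype <- match.arg(dtype)
  stack <- as_image_stack(stack)
  v <- stack$voxels
  d <- dim(v); C <- d[1]; F <- d[2]; H <- d[3]; W <- d[4]
  if (dtype == "uint16") {
    if (min(v) < 0 || max(v) > 1)
      fa_stop(sprintf(
        "uint16 TIFF requires values in [0,1]; got range [%g, %g]",
        min(v), max(v)))
    vq <- round(v * 65535)
  }
  sample_fmt <- if (dtype == "float32") 3L else 1L
  bits <- if (dtype == "float32") 32L else 16L
  bytes_per_page <- W * H * C * bits / 8
  page_bytes <- vector("list", F)
  for (f in seq_len(F)) {
    page <- if (dtype == "uint16") vq[, f, , , drop = FALSE] else
      v[, f, , , drop = FALSE]
    dim(page) <- c(C, H, W)
    pvec <- as.vector(aperm(page, c(1, 3, 2)))  # (c, w, h) fastest-first
    page_bytes[[f]] <- if (dtype == "float32") {
      writeBin(as.numeric(pvec), raw(), size = 4L, endian = "little")
    } else {
      as.raw(as.vector(rbind(pvec %% 256, pvec %/% 256)))
    }
  }
  data_start <- 8
  strip_offsets <- data_start + cumsum(c(0, rep(bytes_per_page, F - 1)))
  ifd0 <- data_start + F * bytes_per_page
  if (ifd0 %% 2 == 1) ifd0 <- ifd0 + 1
  ifds <- list()
  off <- ifd0
  for (f in seq_len(F)) {
    env <- new.env(); env$overflow <- list()
    entries <- list(
      .tiff_pack_entry(256L, 4L, W, env),
      .tiff_pack_entry(257L, 4L, H, env),
      .tiff_pack_entry(258L, 3L, rep(bits, C), env),
      .tiff_pack_entry(259L, 3L, 1L, env),
      .tiff_pack_entry(262L, 3L, 1L, env),
      .tiff_pack_entry(273L, 4L, strip_offsets[f], env),
      .tiff_pack_entry(277L, 3L, C, env),
      .tiff_pack_entry(278L, 4L, H, env),
      .tiff_pack_entry(279L, 4L, bytes_per_page, env),
      .tiff_pack_entry(284L, 3L, 1L, env),
      .tiff_pack_entry(339L, 3L, rep(sample_fmt, C), env)
    )
    n_ent <- length(entries)
    core_len <- 2 + n_ent * 12 + 4
    ## place overflow arrays right after the IFD core, patch their offsets
    ov_off <- off + core_len
    body <- do.call(c, entries)
    ov_bytes <- raw(0)
    for (ov in env$overflow) {
      idx <- which(vapply(seq_len(n_ent), function(i) {
        .rd_int(body[((i - 1) * 12 + 1):((i - 1) * 12 + 2)], "little") == ov$tag
      }, logical(1)))[1]
      body[((idx - 1) * 12 + 9):((idx - 1) * 12 + 12)] <-
        .le4(ov_off + length(ov_bytes))
      ov_bytes <- c(ov_bytes, ov$bytes)
    }
    ifds[[f]] <- list(off = off, n_ent = n_ent, body = body,
                      ov_bytes = ov_bytes)
    off <- ov_off + length(ov_bytes)
    if (off %% 2 == 1) off <- off + 1
  }
  con <- tryCatch(file(path, "wb"), error = function(e)
    fa_stop(paste0("cannot open for writing: ", path), "faunet_io_error"))
  on.exit(close(con))
  writeBin(c(charToRaw("II"), .le2(42), .le4(ifd0)), con)
  for (f in seq_len(F)) writeBin(page_bytes[[f]], con)
  if ((data_start + F * bytes_per_page) %% 2 == 1) writeBin(as.raw(0), con)
  for (f in seq_len(F)) {
    ifd <- ifds[[f]]
    next_off <- if (f < F) ifds[[f + 1]]$off else 0
    writeBin(c(.le2(ifd$n_ent), ifd$body, .le4(next_off), ifd$ov_bytes), con)
    written <- ifd$off + 2 + ifd$n_ent * 12 + 4 + length(ifd$ov_bytes)
    if (f < F && written %% 2 == 1) writeBin(as.raw(0), con)
  }
  invisible(path)
}
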