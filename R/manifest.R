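## Dataset manifests: plain-text (TSV) listing of stack pairs with splits.

#' Construct a dataset manifest
#'
#' @param entries data.frame with columns `pair_id`, `low_path`,
#'   `high_path`, `split` (train/val/test) and `tags` (comma-separated
#'   string, may be empty).
#' @param dir directory that relative paths are resolved against.
#' @export
manifest <- function(entries = NULL, dir = ".") {
  if (is.null(entries)) {
    entries <- data.frame(pair_id = character(), low_path = character(),
                          high_path = character(), split = character(),
                          tags = character(), stringsAsFactors = FALSE)
  }
  need <- c("pair_id", "low_path", "high_path", "split", "tags")
  fa_assert(all(need %in% names(entries)),
            paste0("manifest needs columns: ", paste(need, collapse = ", ")))
  entries <- entries[, need, drop = FALSE]
  entries[] <- lapply(entries, as.character)
  if (anyDuplicated(entries$pair_id))
    fa_stop(paste0("duplicate pair_id in manifest: ",
                   paste(unique(entries$pair_id[duplicated(entries$pair_id)]),
                         collapse = ", ")))
  bad <- setdiff(unique(entries$split), c("train", "val", "test"))
  if (length(bad) > 0)
    fa_stop(paste0("unknown split tag(s): ", paste(bad, collapse = ", ")))
  structure(list(entries = entries, dir = dir), class = "faunet_manifest")
}

#' @export
print.faunet_manifest <- function(x, ...) {
  tab <- table(factor(x$entries$split, levels = c("train", "val", "test")))
  cat(sprintf("<faunet_manifest> %d pairs (train %d / val %d / test %d) in %s\n",
              nrow(x$entries), tab["train"], tab["val"], tab["test"], x$dir))
  invisible(x)
}

.manifest_path <- function(m, p) {
  ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(m$dir, p))
}

#' Save a manifest as a TSV file
#'
#' @param manifest a [manifest].
#' @param path output path; entry paths are written as stored (relative
#'   paths stay relative, resolved against the manifest's directory on
#'   load).
#' @export
save_manifest <- function(manifest, path) {
  fa_assert(inherits(manifest, "faunet_manifest"), "expected a manifest")
  utils::write.table(manifest$entries, file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a manifest from a TSV file
#'
#' @param path manifest file.
#' @param check_paths verify that every referenced stack exists; missing
#'   files raise one error listing them all.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path))
    fa_stop(paste0("no such manifest: ", path), "faunet_io_error")
  entries <- utils::read.table(path, sep = "\t", header = TRUE,
                               colClasses = "character", quote = "",
                               comment.char = "")
  if (nrow(entries) > 0 && !"tags" %in% names(entries)) entries$tags <- ""
  if (nrow(entries) > 0) entries$tags[is.na(entries$tags)] <- ""
  m <- manifest(entries, dir = dirname(path))
  if (check_paths && nrow(m$entries) > 0) {
    paths <- c(.manifest_path(m, m$entries$low_path),
               .manifest_path(m, m$entries$high_path))
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0)
      fa_stop(paste0("manifest references missing file(s): ",
                     paste(missing, collapse = ", ")), "faunet_io_error")
  }
  m
}

#' Subset a manifest by split
#' @param manifest a [manifest].
#' @param split `"train"`, `"val"` or `"test"`.
#' @export
manifest_split <- function(manifest, split) {
  fa_assert(inherits(manifest, "faunet_manifest"), "expected a manifest")
  out <- manifest
  out$entries <- manifest$entries[manifest$entries$split == split, ,
                                  drop = FALSE]
  out
}

#' Load one pair referenced by a manifest
#' @param manifest a [manifest].
#' @param i row index or pair_id.
#' @param axis_label frame-axis label for the loaded stacks.
#' @export
load_pair <- function(manifest, i, axis_label = "Z") {
  fa_assert(inherits(manifest, "faunet_manifest"), "expected a manifest")
  e <- manifest$entries
  if (is.character(i)) i <- match(i, e$pair_id)
  fa_assert(!is.na(i) && i >= 1 && i <= nrow(e), "no such manifest entry")
  stack_pair(read_stack(.manifest_path(manifest, e$low_path[i]), axis_label),
             read_stack(.manifest_path(manifest, e$high_path[i]), axis_label),
             e$pair_id[i])
}
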