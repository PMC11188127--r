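## Shared plumbing: condition classes, logging, seeded RNG, parameter trees.

#' Signal a classed faunet error
#'
#' All declared failure modes raise classed conditions so callers (and the
#' CLI) can map them to exit codes: `faunet_usage_error` (2),
#' `faunet_config_error` (3), `faunet_io_error` (4), `faunet_numeric_error`
#' (5).  Value/format problems with data are `faunet_value_error` (treated
#' as config-class by the CLI).
#'
#' @param msg message string.
#' @param class condition subclass.
#' @keywords internal
fa_stop <- function(msg, class = "faunet_value_error") {
  stop(structure(
    class = c(class, "faunet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

fa_assert <- function(cond, msg, class = "faunet_value_error") {
  if (!isTRUE(cond)) fa_stop(msg, class)
  invisible(TRUE)
}

.fa_log_env <- new.env(parent = emptyenv())
.fa_log_env$level <- 2L  # 1 debug, 2 info, 3 warn, 4 error, 5 quiet
.fa_log_env$file <- NULL

#' Configure logging
#'
#' Messages go to stderr with a timestamp and level; optionally also to a
#' file.
#'
#' @param level one of "debug", "info", "warn", "error", "quiet".
#' @param file optional path of a logfile to append to (`NULL` disables).
#' @return invisibly, the previous settings.
#' @export
fa_log_setup <- function(level = c("info", "debug", "warn", "error", "quiet"),
                         file = NULL) {
  level <- match.arg(level)
  old <- list(level = .fa_log_env$level, file = .fa_log_env$file)
  .fa_log_env$level <- match(level, c("debug", "info", "warn", "error", "quiet"))
  .fa_log_env$file <- file
  invisible(old)
}

fa_log <- function(lvl_num, lvl_name, ...) {
  if (lvl_num < .fa_log_env$level) return(invisible(NULL))
  line <- sprintf("[%s] %-5s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  lvl_name, paste0(...))
  cat(line, "\n", file = stderr(), sep = "")
  if (!is.null(.fa_log_env$file)) {
    cat(line, "\n", file = .fa_log_env$file, sep = "", append = TRUE)
  }
  invisible(NULL)
}

log_debug <- function(...) fa_log(1L, "DEBUG", ...)
log_info <- function(...) fa_log(2L, "INFO", ...)
log_warn <- function(...) fa_log(3L, "WARN", ...)

#' Derive a child seed from a master seed and an index path
#'
#' One master seed drives every source of randomness; sub-streams (per
#' phantom, per epoch, per batch, ...) get seeds derived by folding the
#' index path into a 31-bit LCG state, so e.g. adding epochs never shifts
#' the batches of earlier epochs.
#'
#' @param seed master seed (integer).
#' @param ... integer indices identifying the sub-stream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- as.numeric(seed) %% m
  for (k in c(...)) {
    # all intermediates < 2^53, exact in doubles
    s <- (s * 48271 + as.numeric(k) * 8191 + 1) %% m
  }
  as.integer(s %% (m - 1)) + 1L
}

#' Evaluate an expression under a fixed RNG seed, restoring state after
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## ---- parameter trees ------------------------------------------------------

## Model parameters are nested lists whose leaves are numeric arrays.  The
## optimizer works on the flattened vector; unflatten restores the tree.

flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  fill <- function(node) {
    if (is.list(node)) return(lapply(node, fill))
    n <- length(node)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(out) <- attributes(node)
    out
  }
  out <- fill(skeleton)
  fa_assert(pos == length(vec), "parameter vector length mismatch")
  out
}

## map a binary function over two parameter trees with identical structure
map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(map2_params, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    return(out)
  }
  r <- f(a, b)
  attributes(r) <- attributes(a)
  r
}
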