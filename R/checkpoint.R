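## Checkpoint persistence: a single-file archive holding the model config,
## all weight tensors, the training config, history, stage and lineage.

#' Save a checkpoint
#' @param checkpoint a `faunet_checkpoint`.
#' @param path output file (conventionally `.ckpt`).
#' @export
save_checkpoint <- function(checkpoint, path) {
  fa_assert(inherits(checkpoint, "faunet_checkpoint"),
            "expected a checkpoint", "faunet_config_error")
  tryCatch(saveRDS(checkpoint, path),
           error = function(e) fa_stop(
             paste0("cannot write checkpoint: ", path), "faunet_io_error"))
  invisible(path)
}

#' Load a checkpoint
#' @param path checkpoint file.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    fa_stop(paste0("no such checkpoint: ", path), "faunet_io_error")
  ck <- readRDS(path)
  fa_assert(inherits(ck, "faunet_checkpoint") &&
              !is.null(ck$format_version),
            paste0("not a faunet checkpoint: ", path))
  nw <- length(flatten_params(ck$model$weights))
  fa_assert(nw == parameter_count(ck$model$config),
            "checkpoint weights inconsistent with its config")
  fa_assert(all(is.finite(flatten_params(ck$model$weights))),
            "checkpoint contains non-finite weights")
  ck
}

#' Inspect a checkpoint without touching its weights
#'
#' @param path checkpoint file.
#' @return list with `format_version`, `stage`, `parent_id`, the model
#'   and train configs, parameter count and history.
#' @export
checkpoint_info <- function(path) {
  ck <- load_checkpoint(path)
  list(format_version = ck$format_version, stage = ck$stage,
       parent_id = ck$parent_id, model_config = ck$model$config,
       train_config = ck$train_config,
       n_parameters = length(flatten_params(ck$model$weights)),
       epochs_trained = nrow(ck$history), history = ck$history)
}

#' @export
print.faunet_checkpoint <- function(x, ...) {
  cat(sprintf("<faunet_checkpoint> stage=%s, %d epochs trained%s\n",
              x$stage, nrow(x$history),
              if (!is.null(x$parent_id))
                paste0(", parent ", substr(x$parent_id, 1, 8)) else ""))
  print(x$model)
  invisible(x)
}
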