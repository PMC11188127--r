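## Evaluation harnesses: per-pair quality reports, the repetition-average
## robustness curve, and the fine-tune-vs-scratch comparison.

#' Evaluate a model over a manifest split
#'
#' For each pair: run [infer] on the low-SNR member and compute PSNR and
#' SSIM3D of both the input and the output against the high-SNR member.
#' Deterministic given the checkpoint.
#'
#' @param checkpoint a `faunet_checkpoint`.
#' @param manifest a [manifest].
#' @param split which split to evaluate (default `"test"`).
#' @param tiling optional [tiling_spec].
#' @param data_range intensity range for the metrics (stacks are scored
#'   on their stored scale).
#' @return a `faunet_eval_report` with `per_pair` rows and a `summary`
#'   (mean and sd of each metric column).
#' @export
evaluate_pairs <- function(checkpoint, manifest, split = "test",
                           tiling = NULL, data_range = 1) {
  ms <- manifest_split(manifest, split)
  fa_assert(nrow(ms$entries) > 0,
            paste0("no entries in split '", split, "'"),
            "faunet_config_error")
  rows <- lapply(seq_len(nrow(ms$entries)), function(i) {
    pr <- load_pair(ms, i)
    out <- infer(checkpoint, pr$low, tiling)
    data.frame(pair_id = pr$pair_id,
               psnr_input = psnr(pr$low, pr$high, data_range),
               psnr_output = psnr(out, pr$high, data_range),
               ssim3d_input = ssim3d(pr$low, pr$high,
                                     data_range = data_range),
               ssim3d_output = ssim3d(out, pr$high,
                                      data_range = data_range),
               stringsAsFactors = FALSE)
  })
  per_pair <- do.call(rbind, rows)
  cols <- c("psnr_input", "psnr_output", "ssim3d_input", "ssim3d_output")
  summary <- data.frame(
    metric = cols,
    mean = vapply(cols, function(cl) mean(per_pair[[cl]]), numeric(1)),
    sd = vapply(cols, function(cl) stats::sd(per_pair[[cl]]), numeric(1)),
    row.names = NULL)
  structure(list(per_pair = per_pair, summary = summary,
                 split = split,
                 config_hash = checkpoint_hash(checkpoint),
                 seed = checkpoint$train_config$seed),
            class = "faunet_eval_report")
}

#' @export
print.faunet_eval_report <- function(x, ...) {
  cat(sprintf("<faunet_eval_report> %d pairs (%s split)\n",
              nrow(x$per_pair), x$split))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Robustness curve over a repetition-average series
#'
#' Runs the model on the Avg-n member for each requested n and scores the
#' input and output both against the synthetic clean stack (oracle) and
#' against member N (the acquisition-style ground truth) — real series
#' have only the latter, and its own noise floor biases PSNR, so both
#' references are kept.
#'
#' @param checkpoint a `faunet_checkpoint`.
#' @param series a `faunet_avg_series` from [make_average_series].
#' @param n_values which Avg-n members to evaluate.
#' @param tiling optional [tiling_spec].
#' @param data_range metric intensity range.
#' @return data.frame with columns `n_average`, `psnr_in`, `psnr_out`,
#'   `ssim_in`, `ssim_out` (clean-referenced) and `psnr_in_gt`,
#'   `psnr_out_gt` (member-N-referenced).
#' @export
robustness_curve <- function(checkpoint, series,
                             n_values = c(1, 4, 8, 16, 32, 64),
                             tiling = NULL, data_range = 1) {
  fa_assert(inherits(series, "faunet_avg_series"),
            "expected a faunet_avg_series", "faunet_config_error")
  N <- series$ground_truth_index
  fa_assert(all(n_values >= 1 & n_values <= N),
            "n_values outside the series")
  gt <- series$members[[N]]
  rows <- lapply(sort(n_values), function(n) {
    inp <- series$members[[n]]
    out <- infer(checkpoint, inp, tiling)
    data.frame(n_average = n,
               psnr_in = psnr(inp, series$clean, data_range),
               psnr_out = psnr(out, series$clean, data_range),
               ssim_in = ssim3d(inp, series$clean, data_range = data_range),
               ssim_out = ssim3d(out, series$clean,
                                 data_range = data_range),
               psnr_in_gt = psnr(inp, gt, data_range),
               psnr_out_gt = psnr(out, gt, data_range))
  })
  do.call(rbind, rows)
}

#' Compare fine-tuning against training from scratch
#'
#' For each seed: fine-tune the backbone on the manifest's train split,
#' and train an identically configured model from scratch with an
#' identical budget; evaluate both arms on the test split.
#'
#' @param backbone a backbone `faunet_checkpoint`.
#' @param manifest the new-domain [manifest] (few train pairs, a test
#'   split).
#' @param train_config shared [train_config]; the scratch arm uses
#'   `learning_rate`, the fine-tune arm `lr_finetune`.
#' @param n_seeds number of replicate seeds (>= 3 for a stable mean).
#' @param tiling optional [tiling_spec].
#' @return list with `per_seed` (one row per seed and arm) and `summary`
#'   (mean PSNR/SSIM per arm).
#' @export
finetune_vs_scratch <- function(backbone, manifest, train_config,
                                n_seeds = 3L, tiling = NULL) {
  fa_assert(n_seeds >= 1, "n_seeds must be >= 1", "faunet_config_error")
  rows <- list()
  for (s in seq_len(n_seeds)) {
    tc <- train_config
    tc$seed <- derive_seed(train_config$seed, 100L, s)
    ft <- finetune(backbone, manifest, tc)
    sc <- train_backbone(manifest, backbone$model$config, tc)
    for (arm in c("finetuned", "scratch")) {
      ck <- if (arm == "finetuned") ft else sc
      rep_ <- evaluate_pairs(ck, manifest, "test", tiling)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = tc$seed, arm = arm,
        psnr = mean(rep_$per_pair$psnr_output),
        ssim = mean(rep_$per_pair$ssim3d_output),
        psnr_input = mean(rep_$per_pair$psnr_input),
        val_loss = ck$history$val_loss[nrow(ck$history)])
    }
  }
  per_seed <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_seed, per_seed$arm),
                                   function(df) data.frame(
                                     arm = df$arm[1],
                                     mean_psnr = mean(df$psnr),
                                     mean_ssim = mean(df$ssim))))
  row.names(summary) <- NULL
  list(per_seed = per_seed, summary = summary)
}
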