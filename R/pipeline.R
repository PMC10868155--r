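#' Run the full network-inference pipeline
#'
#' Orchestrates the end-to-end workflow on one expression matrix:
#' preprocessing (log2 and row-max scaling), autoencoder training,
#' pairwise latent-space correlation, and — when a gold standard is
#' supplied — benchmarking plus score calibration into posterior
#' probabilities. All outputs are written to `output_dir` alongside a
#' resolved copy of the configuration and the training loss history, so
#' any run can be reproduced from its output directory alone.
#'
#' Files written: `network.tsv` (ranked network; calibrated version as
#' `network_calibrated.tsv` when a gold standard is given), `curve.tsv`
#' (cumulative TP/FP points), `calibration.json` (fitted a0..a4 and SSE),
#' `loss_history.tsv`, and `run_config.json`.
#'
#' @param input Path to an expression matrix (any [read_matrix()] format)
#'   or an in-memory expression matrix.
#' @param output_dir Directory for outputs; created if needed.
#' @param config A [vae_config()].
#' @param format Matrix format passed to [read_matrix()].
#' @param log2_transform Apply log2(x+1) before scaling (default `TRUE`;
#'   set `FALSE` for already-logged intensities).
#' @param score_floor,top_n Network output controls (see [pairwise_pcc()]
#'   and [filter_network()]).
#' @param gold Optional `vaenet_gold` object or path to a membership TSV;
#'   triggers benchmarking and calibration.
#' @param window,step Sliding-window settings for calibration points; both
#'   are capped to the number of evaluable pairs when the network is
#'   small.
#' @param prefixes Evaluable-prefix sizes for the benchmark summary.
#' @param verbose Print progress (default `TRUE`).
#' @return Invisibly, a list with `network`, `latent`, and (when `gold`
#'   is given) `curve`, `calibration`, `calibrated`.
#' @export
run_pipeline <- function(input, output_dir, config = vae_config(),
                         format = "auto", log2_transform = TRUE,
                         score_floor = -1, top_n = NULL, gold = NULL,
                         window = 1000L, step = 100L, prefixes = 10000L,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  m <- if (is.character(input)) read_matrix(input, format = format) else
    input
  assert_expression_matrix(m)

  say("[preprocess] ", nrow(m), " genes x ", ncol(m), " conditions")
  scaled <- preprocess_matrix(m, log2_transform = log2_transform)
  zr <- attr(scaled, "zero_rows")
  if (length(zr)) say("[preprocess] ", length(zr), " all-zero gene(s)")

  say("[vae] training: hidden ", config$hidden_dim, ", latent ",
      config$latent_dim, ", ", config$epochs, " epochs, seed ",
      config$seed)
  latent <- train_vae(scaled, config, verbose = FALSE)
  data.table::fwrite(latent$loss_history,
                     file.path(output_dir, "loss_history.tsv"), sep = "\t")

  say("[network] pairwise latent-space correlation")
  net <- pairwise_pcc(latent, score_floor = score_floor)
  if (!is.null(top_n)) net <- filter_network(net, top_n = top_n)
  write_network(net, file.path(output_dir, "network.tsv"))

  out <- list(network = net, latent = latent)
  if (!is.null(gold)) {
    if (is.character(gold)) gold <- read_gold_standard(gold, "membership")
    say("[benchmark] cumulative TP/FP curve")
    curve <- cumulative_curve(net, gold, prefixes = prefixes)
    write_curve(curve, file.path(output_dir, "curve.tsv"))
    n_eval <- nrow(curve$points)
    w <- min(window, n_eval)
    s <- min(step, max(1L, w %/% 10L))
    say("[calibrate] window ", w, ", step ", s)
    pts <- window_points(curve, window = w, step = s)
    calib <- fit_calibration(pts)
    jsonlite::write_json(
      list(params = as.list(calib$params), sse = calib$sse,
           converged = calib$converged, window = w, step = s),
      file.path(output_dir, "calibration.json"),
      auto_unbox = TRUE, digits = NA)
    calibrated <- calibrate_network(net, calib)
    write_network(calibrated,
                  file.path(output_dir, "network_calibrated.tsv"))
    out <- c(out, list(curve = curve, calibration = calib,
                       calibrated = calibrated))
  }

  cfg <- c(unclass(config),
           list(log2_transform = log2_transform,
                score_floor = score_floor,
                top_n = if (is.null(top_n)) NULL else top_n,
                window = window, step = step,
                n_genes = nrow(m), n_conditions = ncol(m),
                package_version = as.character(
                  utils::packageVersion("vaenet"))))
  jsonlite::write_json(cfg, file.path(output_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("[done] outputs in ", output_dir)
  invisible(out)
}
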