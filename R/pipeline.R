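#' Validate and complete a pipeline configuration
#'
#' Fills defaults for every stage of the workflow (simulation or file
#' input, preprocessing, connectivity, link prediction, dynamics) and
#' rejects out-of-range values with field-level messages. Defaults follow
#' the workflow's standard operating point: 50 Hz notch, 8000 uV amplitude
#' limit, the five canonical bands, 6-cycle windows, 0.3 binarization
#' threshold, RA index, train ratios 0.70..0.95, 100 repetitions, 3-minute
#' preictal/postictal margins.
#'
#' @param raw named list of overrides (possibly empty).
#' @return completed list of class `pipeline_config`.
#' @export
validate_config <- function(raw = list()) {
  defaults <- list(
    input_prefix = NULL,          # read_recording() prefix; NULL = simulate
    simulation = NULL,            # simulation_config(); NULL = default config
    segment_plan = NULL,          # simulate_seizure_eeg() default plan
    notch_hz = 50,
    amplitude_limit_uV = 8000,
    denoise = TRUE,
    bands = "canonical",
    n_cycles = 6,
    threshold = 0.3,
    index = "RA",
    ratios = seq(0.70, 0.95, by = 0.05),
    n_repetitions = 100,
    pre_s = 180,
    post_s = 180,
    run_benchmark = FALSE,
    seed = 1)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop_config("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  if (!(cfg$threshold >= 0 && cfg$threshold < 1))
    stop_config("threshold: must lie in [0, 1), got %g", cfg$threshold)
  if (any(cfg$ratios <= 0 | cfg$ratios > 0.95))
    stop_config("ratios: train ratios must lie in (0, 0.95]")
  if (cfg$notch_hz <= 0) stop_config("notch_hz: must be positive")
  if (cfg$amplitude_limit_uV <= 0) stop_config("amplitude_limit_uV: must be positive")
  if (cfg$n_cycles <= 0) stop_config("n_cycles: must be positive")
  if (cfg$n_repetitions < 1) stop_config("n_repetitions: must be >= 1")
  if (!cfg$index %in% c("CN", "RA", "AA", "Sorenson"))
    stop_config("index: must be one of CN, RA, AA, Sorenson")
  if (identical(cfg$bands, "canonical")) cfg$bands <- canonical_bands()
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full seizure-dynamics workflow
#'
#' Orchestrates every stage: obtain a recording (simulate with the config
#' seed, or read `input_prefix`), preprocess (wavelet denoise, notch,
#' amplitude mask), segment conditions around the seizure markers,
#' decompose into subbands, build per-band PLV network series, compute
#' per-window RA node sequences, their consecutive variation and
#' cross-condition distributions, and the node index summation. All
#' numeric outputs are written as CSV under `out_dir` together with a
#' reproducibility manifest (`manifest.json`: config, config hash, seed,
#' package and R versions, window counts). Optionally benchmarks the four
#' indices on the recording's gamma-band mid-seizure network.
#'
#' @param config a [validate_config()] result (or a raw list passed
#'   through it).
#' @param out_dir output directory, created if missing; NULL skips file
#'   output.
#' @return (invisibly) list with the recording, segmentation, network
#'   series, per-band sequences/variation/summation tables and manifest.
#' @export
run_pipeline <- function(config = validate_config(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)

  # --- input stage
  if (is.null(config$input_prefix)) {
    sim <- config$simulation
    if (is.null(sim)) sim <- simulation_config(seed = config$seed)
    rec <- if (is.null(config$segment_plan)) simulate_seizure_eeg(sim)
           else simulate_seizure_eeg(sim, config$segment_plan)
  } else {
    rec <- read_recording(config$input_prefix)
  }

  # --- preprocessing stage
  if (config$denoise) rec <- wavelet_denoise(rec)
  rec <- remove_powerline(rec, config$notch_hz)
  rec <- reject_amplitude_artifacts(rec, config$amplitude_limit_uV)
  if (!nrow(rec$seizures))
    stop_config("segmentation stage: recording has no seizure markers")
  segmentation <- segment_conditions(rec, config$pre_s, config$post_s)

  # --- connectivity stage
  banded <- bandpass_decompose(rec, config$bands)
  series <- build_network_series(banded, segmentation, config$n_cycles)

  # --- dynamics stage (per band)
  per_band <- lapply(series, function(s) {
    seqs <- window_node_sequences(s, index = config$index,
                                  threshold = config$threshold)
    list(
      sequences = seqs,
      variation = variation_series(seqs),
      cross = tryCatch(
        variation_series(seqs, mode = "cross_condition",
                         cond_a = "preictal", cond_b = "ictal"),
        error = function(e) NULL),
      summation = node_index_summation(seqs))
  })

  # --- optional link-prediction benchmark on the ictal gamma network
  bench <- NULL
  if (isTRUE(config$run_benchmark)) {
    gser <- series[[length(series)]]
    ict <- which(gser$windows$condition == "ictal")
    if (length(ict)) {
      g <- graph_from_binary_adjacency(
        binarize(gser$adjacency[[ict[ceiling(length(ict) / 2)]]],
                 config$threshold))
      if (igraph::ecount(g) >= 2)
        bench <- benchmark(list(eeg_gamma = g), ratios = config$ratios,
                           n_repetitions = config$n_repetitions,
                           seed = config$seed)
    }
  }

  cfg_json <- jsonlite::toJSON(unclass(config)[
    !vapply(unclass(config), is.function, TRUE)], auto_unbox = TRUE,
    digits = NA, force = TRUE, null = "null")
  manifest <- list(
    package = "epinetdyn",
    version = as.character(utils::packageVersion("epinetdyn")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
    config_hash = config_hash(cfg_json),
    n_windows = as.list(vapply(series, function(s) nrow(s$windows), 0L)),
    n_skipped = as.list(vapply(series, function(s) nrow(s$skipped), 0L)))

  result <- list(recording = rec, segmentation = segmentation,
                 series = series, per_band = per_band,
                 benchmark = bench, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    seq_rows <- list(); var_rows <- list(); cross_rows <- list(); sum_rows <- list()
    for (bn in names(per_band)) {
      pb <- per_band[[bn]]
      w <- attr(pb$sequences, "windows")
      sq <- as.data.frame(pb$sequences)
      names(sq) <- paste0("seq_", seq_len(ncol(sq)))
      seq_rows[[bn]] <- cbind(band = bn, window = seq_len(nrow(sq)),
                              start_s = (w$start - 1) / rec$fs,
                              condition = w$condition, sq,
                              index_sum = pb$summation$per_window$index_sum)
      var_rows[[bn]] <- cbind(band = bn, pb$variation)
      if (!is.null(pb$cross))
        cross_rows[[bn]] <- cbind(band = bn, cond_a = "preictal",
                                  cond_b = "ictal", pb$cross)
      sum_rows[[bn]] <- cbind(band = bn, pb$summation$per_condition)
    }
    write.csv(do.call(rbind, seq_rows), file.path(out_dir, "node_sequences.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, var_rows), file.path(out_dir, "sequence_variation.csv"),
              row.names = FALSE)
    if (length(cross_rows))
      write.csv(do.call(rbind, cross_rows),
                file.path(out_dir, "cross_condition_variation.csv"),
                row.names = FALSE)
    write.csv(do.call(rbind, sum_rows),
              file.path(out_dir, "node_index_summation.csv"), row.names = FALSE)
    if (!is.null(bench))
      write.csv(bench, file.path(out_dir, "linkpred_benchmark.csv"),
                row.names = FALSE)
  }
  invisible(result)
}
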