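# Experiment configuration: presets mirroring the two reference corpus
# geometries, schema validation, serialization, and the staged pipeline
# runner used by the command-line interface.

#' Build a preset experiment configuration
#'
#' `"deap_like"`: 32 subjects x 40 trials x 32 channels at 128 Hz, 63-s
#' trials with the first 3 s trimmed, binary labels, conv kernels (32, 64),
#' head layers (512, 256, 2). `"seed_like"`: 15 subjects x 15 trials x 62
#' channels at 200 Hz, 80-s segments, 3-class labels, conv kernels (8, 16),
#' head output 3 (softmax, adam optimizer). Any field can be overridden,
#' which is how the scaled-down desk-size experiments are configured.
#'
#' @param name `"deap_like"` or `"seed_like"`.
#' @param ... overrides of top-level fields (e.g. `n_subjects = 4`,
#'   `effect_size = 0`, `stage = stage_config(...)`).
#' @return object of class `experiment_config`.
#' @export
preset_config <- function(name = c("deap_like", "seed_like"), ...) {
  name <- match.arg(name)
  base <- if (name == "deap_like") {
    list(
      preset = name,
      n_subjects = 32L, n_trials = 40L, n_channels = 32L,
      fs = 128, duration = 63, trim_s = 3, n_classes = 2L,
      window_s = 8, step_s = 4,
      feature_kind = "pcc",
      band_edges = default_bands(),
      n_latent_sources = 4L, effect_size = 1, noise_sd = 1,
      conv = conv_spec(kernels_per_layer = c(32L, 64L)),
      sae = sae_spec(),
      dnn = dnn_spec(n_out = 2L),
      stage = stage_config(),
      data_seed = 1L
    )
  } else {
    list(
      preset = name,
      n_subjects = 15L, n_trials = 15L, n_channels = 62L,
      fs = 200, duration = 80, trim_s = 0, n_classes = 3L,
      window_s = 8, step_s = 4,
      feature_kind = "pcc",
      band_edges = default_bands(),
      n_latent_sources = 4L, effect_size = 1, noise_sd = 1,
      conv = conv_spec(kernels_per_layer = c(8L, 16L)),
      sae = sae_spec(),
      dnn = dnn_spec(n_out = 3L),
      stage = stage_config(dnn = list(epochs = 100, batch = 128, lr = 0.01,
                                      optimizer = "adam")),
      data_seed = 1L
    )
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown) > 0) stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  base[names(overrides)] <- overrides
  validate_config(structure(base, class = "experiment_config"))
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!cfg$feature_kind %in% c("pcc", "pca", "sc")) {
    stopf("feature_kind must be pcc, pca or sc")
  }
  validate_band_edges(cfg$band_edges, cfg$fs)
  if (cfg$n_classes != cfg$dnn$n_out && !(cfg$n_classes == 2 && cfg$dnn$n_out %in% 1:2)) {
    stopf("head n_out = %d incompatible with %d classes", cfg$dnn$n_out, cfg$n_classes)
  }
  if (cfg$window_s > cfg$duration - cfg$trim_s) {
    stopf("window (%g s) longer than trimmed trial (%g s)",
          cfg$window_s, cfg$duration - cfg$trim_s)
  }
  cfg
}

#' Synthetic-data spec implied by a configuration
#'
#' @param cfg an `experiment_config`.
#' @return the corresponding [synth_spec()].
#' @export
config_synth_spec <- function(cfg) {
  synth_spec(
    n_subjects = cfg$n_subjects, n_trials_per_subject = cfg$n_trials,
    n_channels = cfg$n_channels, fs = cfg$fs, duration = cfg$duration,
    n_classes = cfg$n_classes, n_latent_sources = cfg$n_latent_sources,
    band_edges = cfg$band_edges, effect_size = cfg$effect_size,
    noise_sd = cfg$noise_sd, seed = cfg$data_seed
  )
}

config_to_list <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(cfg)
}

#' Serialize / restore an experiment configuration
#'
#' Round-trippable JSON serialization; every pipeline run writes its
#' resolved configuration next to its outputs.
#'
#' @param cfg an `experiment_config`.
#' @param path file path.
#' @return `read_config` returns the restored `experiment_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(config_to_list(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- preset_config(raw$preset)
  simple <- c("n_subjects", "n_trials", "n_channels", "fs", "duration",
              "trim_s", "n_classes", "window_s", "step_s", "feature_kind",
              "n_latent_sources", "effect_size", "noise_sd", "data_seed")
  for (f in simple) cfg[[f]] <- if (is.integer(cfg[[f]])) as.integer(raw[[f]]) else raw[[f]]
  cfg$band_edges <- if (is.matrix(raw$band_edges)) {
    lapply(seq_len(nrow(raw$band_edges)), function(i) raw$band_edges[i, ])
  } else raw$band_edges
  cfg$conv <- do.call(conv_spec, raw$conv[c("kernels_per_layer", "kernel_len",
                                            "pool", "dropout_rate", "activation")])
  cfg$sae <- do.call(sae_spec, raw$sae[c("encode_units", "hidden_units",
                                         "decode_units", "rho", "beta", "activation")])
  cfg$dnn <- do.call(dnn_spec, raw$dnn[c("layer_units", "n_out", "activation")])
  st <- raw$stage[c("cnn", "sae", "dnn", "baseline",
                    "split_fraction", "split_seed", "init_seed", "mode")]
  for (blk in c("cnn", "sae", "dnn", "baseline")) {
    if (length(st[[blk]]$optimizer) == 0) st[[blk]]["optimizer"] <- list(NULL)
  }
  cfg$stage <- do.call(stage_config, st)
  validate_config(cfg)
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate -> preprocess (trim, band-decompose, window) ->
#' featurize -> train (baseline and/or composite), writing one artifact per
#' stage under `out_dir` (RDS stage outputs, the resolved config as JSON,
#' per-epoch metrics as CSV, and a segment provenance CSV). A stage whose
#' artifact already exists is reused unless `force = TRUE`, so an
#' interrupted run resumes from the last completed stage.
#'
#' @param cfg an `experiment_config`.
#' @param out_dir output directory (created if missing).
#' @param models subset of `c("baseline", "composite")`.
#' @param force overwrite existing stage artifacts.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the experiment `report` and artifact
#'   paths.
#' @export
run_pipeline <- function(cfg, out_dir, models = c("baseline", "composite"),
                         force = FALSE, quiet = FALSE) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  paths <- list(
    config = file.path(out_dir, "config.json"),
    recording = file.path(out_dir, "recording.rds"),
    segments = file.path(out_dir, "segments.rds"),
    features = file.path(out_dir, "features.rds"),
    provenance = file.path(out_dir, "segment_index.csv"),
    metrics = file.path(out_dir, "metrics.csv"),
    report = file.path(out_dir, "report.json")
  )
  write_config(cfg, paths$config)

  stage <- function(path, label, fn) {
    if (file.exists(path) && !force) {
      say("[%s] reusing %s", label, path)
      readRDS(path)
    } else {
      t0 <- Sys.time()
      x <- fn()
      saveRDS(x, path)
      say("[%s] wrote %s (%.1f s)", label, path,
          as.numeric(Sys.time() - t0, units = "secs"))
      x
    }
  }

  rec <- stage(paths$recording, "simulate", function() {
    generate_recording(config_synth_spec(cfg), preset_name = cfg$preset)
  })
  segs <- stage(paths$segments, "preprocess", function() {
    r <- if (cfg$trim_s > 0) trim_lead(rec, cfg$trim_s) else rec
    segment_windows(decompose_bands(r, cfg$band_edges), cfg$window_s, cfg$step_s)
  })
  rm(rec)  # stages hold large arrays; free each as soon as the next exists
  utils::write.csv(cbind(segs$provenance, label = segs$labels),
                   paths$provenance, row.names = FALSE)
  ft <- stage(paths$features, "featurize", function() {
    featurize(segs, cfg$feature_kind)
  })
  rm(segs)
  invisible(gc(FALSE))

  say("[train] %s on %d samples", paste(models, collapse = " + "), dim(ft$data)[1])
  report <- NULL
  metrics <- NULL
  for (model in models) {
    run <- if (model == "baseline") {
      train_baseline_cnn(ft, cfg$stage, cfg$conv, cfg$dnn)
    } else {
      train_composite(ft, cfg$stage, cfg$conv, cfg$sae, cfg$dnn)
    }
    res <- if (model == "baseline") run else run$result
    report <- rbind(report, data.frame(
      model = model, feature = cfg$feature_kind,
      window_s = cfg$window_s, step_s = cfg$step_s, mode = cfg$stage$mode,
      accuracy = res$final_accuracy, convergence_epoch = res$convergence_epoch,
      data_seed = cfg$data_seed, split_seed = cfg$stage$split_seed,
      init_seed = cfg$stage$init_seed))
    h <- res$history
    metrics <- rbind(metrics, data.frame(model = model, stage = "classifier",
                                         h, row.names = NULL))
    if (model == "composite") {
      sh <- run$sae$history
      metrics <- rbind(metrics, data.frame(
        model = model, stage = "sae", epoch = sh$epoch,
        train_loss = sh$recon_loss, train_acc = NA_real_,
        test_loss = sh$total_cost, test_acc = NA_real_))
    }
    saveRDS(run, file.path(out_dir, sprintf("model_%s.rds", model)))
  }
  utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  say("[done] report: %s", paths$report)
  invisible(list(report = report, paths = paths))
}
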