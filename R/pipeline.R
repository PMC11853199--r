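#' Declarative pipeline configuration
#'
#' A single document collecting every stage's tunables: working sample rate,
#' filter band and family, segment length, entropy bins, wavelet depth,
#' selection significance level, classifier hyperparameters, synthetic-corpus
#' parameters, and the seeds. Values can be loaded from a YAML file and/or
#' overridden programmatically; the result is validated before use and
#' carries a content hash that stages stamp into their artifacts so silent
#' configuration drift is detectable.
#'
#' @param path Optional YAML file with (a subset of) the configuration.
#' @param overrides Named list merged over the file/defaults.
#' @return A validated `pipeline_config` list with attribute `hash`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    seed = 1L,
    sample_rate = 4000,
    filter = list(family = "butterworth", order = 5L, low_cut_hz = 80,
                  high_cut_hz = 1000, ripple_db = 1, attenuation_db = 40),
    segment_seconds = 6,
    entropy_bins = 256L,
    wavelet = "db7",
    levels = 10L,
    selection_alpha = 0.05,
    test_fraction = 0.2,
    balance = TRUE,
    features = "selected",
    model = list(n_hidden = 250L, max_epochs = 1000L, dropout_rate = 0.3,
                 l2_penalty = 1e-4, early_stopping_patience = 50L,
                 validation_fraction = 0.1, batch_size = 32L,
                 learning_rate = 1e-3),
    synthetic = list(duration = 12, breath_cycle_period = 4,
                     base_noise_band = c(100, 900), crackle_rate = 8,
                     wheeze_frequencies = c(250, 420), snr_db = 15,
                     counts_per_class = c(healthy = 40, pneumonia = 40,
                                          copd = 40, other = 40))
  )
  if (!is.null(path)) {
    loaded <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, loaded)
  }
  cfg <- modifyList(cfg, overrides)
  validate_config(cfg)
  attr(cfg, "hash") <- config_hash(as.character(jsonlite::toJSON(
    cfg, auto_unbox = TRUE, digits = NA)))
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  ok <- function(cond, msg) {
    if (!cond) stop_respscreen("invalid config: %s", msg,
                               class = "respscreen_config_error")
  }
  ok(cfg$sample_rate > 0, "sample_rate must be positive")
  ok(cfg$filter$family %in% c("butterworth", "chebyshev1", "chebyshev2",
                              "elliptic"), "unknown filter family")
  ok(cfg$filter$low_cut_hz > 0 &&
       cfg$filter$low_cut_hz < cfg$filter$high_cut_hz &&
       cfg$filter$high_cut_hz < cfg$sample_rate / 2,
     "filter band must lie inside (0, Nyquist)")
  ok(cfg$segment_seconds > 0, "segment_seconds must be positive")
  ok(cfg$entropy_bins >= 2, "entropy_bins must be >= 2")
  ok(cfg$levels >= 1, "levels must be >= 1")
  ok(cfg$selection_alpha > 0 && cfg$selection_alpha < 1,
     "selection_alpha must be in (0, 1)")
  ok(cfg$test_fraction > 0 && cfg$test_fraction < 1,
     "test_fraction must be in (0, 1)")
  ok(is.character(cfg$features) || is.null(cfg$features),
     "features must be 'all', 'selected', or a character vector")
  invisible(cfg)
}

config_filter <- function(cfg) {
  design_filter(cfg$filter$family, cfg$filter$order, cfg$filter$low_cut_hz,
                cfg$filter$high_cut_hz, cfg$sample_rate,
                ripple_db = cfg$filter$ripple_db,
                attenuation_db = cfg$filter$attenuation_db)
}

config_model <- function(cfg) {
  do.call(model_config, c(cfg$model, list(seed = cfg$seed)))
}

config_features <- function(cfg, table) {
  if (is.null(cfg$features) || identical(cfg$features, "all")) {
    feature_columns(table)
  } else if (identical(cfg$features, "selected")) {
    intersect(default_selected_features(), names(table))
  } else {
    cfg$features
  }
}

config_synthetic_spec <- function(cfg) {
  syn <- cfg$synthetic
  synthetic_spec(
    sample_rate = cfg$sample_rate, duration = syn$duration,
    breath_cycle_period = syn$breath_cycle_period,
    base_noise_band = unlist(syn$base_noise_band),
    crackle_rate = syn$crackle_rate,
    wheeze_frequencies = unlist(syn$wheeze_frequencies),
    snr_db = syn$snr_db,
    counts_per_class = unlist(syn$counts_per_class), seed = cfg$seed)
}

artifact_metadata <- function(cfg) {
  c(config_hash = attr(cfg, "hash"), seed = as.character(cfg$seed))
}

load_manifest_recordings <- function(manifest_path, cfg) {
  dir <- dirname(manifest_path)
  manifest <- read_manifest(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$recording_path[i]
    if (!file.exists(p)) p <- file.path(dir, p)
    load_recording(p, target_rate = cfg$sample_rate,
                   subject_id = manifest$subject_id[i],
                   measurement_point = manifest$measurement_point[i],
                   label = manifest$label[i])
  })
}

#' Probabilities of the four classes for one recording
#'
#' Applies the configured preprocessing (filter, normalization, 6-s
#' segmentation) and the trained model to a recording, returning one
#' probability row per segment.
#'
#' @param model A [train_classifier()] or [load_model()] result.
#' @param recording An [audio_recording()].
#' @param cfg A [pipeline_config()].
#' @return Matrix of class probabilities, one row per segment.
#' @export
screen_recording <- function(model, recording, cfg = pipeline_config()) {
  proc <- normalize_recording(apply_filter(config_filter(cfg), recording))
  segs <- segment_recording(proc, cfg$segment_seconds)
  feats <- do.call(rbind, lapply(segs, function(s) {
    extract_feature_vector(s, n_bins = cfg$entropy_bins,
                           wavelet = cfg$wavelet, levels = cfg$levels)
  }))
  predict_proba(model, feats[, model$features, drop = FALSE])
}

#' Run one pipeline stage
#'
#' Command-style entry point mirroring the staged workflow: `simulate`
#' writes a synthetic WAV corpus and manifest; `preprocess` writes filtered
#' and normalized copies of the manifest's recordings; `extract` writes the
#' labeled feature CSV; `select` writes the Kruskal-Wallis ranking and the
#' incremental top-m accuracy curve; `train` fits and archives the
#' classifier; `evaluate` writes one-vs-rest metrics for the held-out split;
#' `screen` writes a screening report for the input recordings. Every CSV
#' artifact embeds the configuration hash and seed as `#` header lines.
#'
#' @param name Stage name.
#' @param config A [pipeline_config()].
#' @param input Stage input path(s): a manifest or directory for
#'   `preprocess`/`extract`/`screen`, a feature CSV for `select`/`train`,
#'   `c(features_csv, model_json)` for `evaluate`, and
#'   `c(manifest_or_wav, model_json)` for `screen`.
#' @param output Output directory (created if needed).
#' @return Invisibly, a named character vector of artifact paths.
#' @export
run_command <- function(name = c("simulate", "preprocess", "extract",
                                 "select", "train", "evaluate", "screen"),
                        config = pipeline_config(), input = NULL,
                        output = ".") {
  name <- match.arg(name)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output, recursive = TRUE, showWarnings = FALSE)
  meta <- artifact_metadata(config)
  need_input <- function() {
    if (is.null(input) || !all(file.exists(input))) {
      stop_respscreen("stage '%s' needs existing input (got: %s)", name,
                      paste(format(input), collapse = ", "),
                      class = "respscreen_io_error")
    }
  }
  as_manifest_path <- function(p) {
    if (dir.exists(p)) file.path(p, "manifest.csv") else p
  }

  artifacts <- switch(name,
    simulate = {
      corpus <- generate_corpus(config_synthetic_spec(config))
      path <- write_corpus(corpus, output)
      c(manifest = path)
    },
    preprocess = {
      need_input()
      manifest_path <- as_manifest_path(input[1])
      recs <- load_manifest_recordings(manifest_path, config)
      manifest <- read_manifest(manifest_path)
      spec <- config_filter(config)
      for (i in seq_along(recs)) {
        proc <- normalize_recording(apply_filter(spec, recs[[i]]))
        save_recording(proc, file.path(output,
                                       basename(manifest$recording_path[i])))
      }
      out_manifest <- manifest
      out_manifest$recording_path <- basename(manifest$recording_path)
      path <- file.path(output, "manifest.csv")
      write_manifest(out_manifest, path)
      c(manifest = path)
    },
    extract = {
      need_input()
      manifest_path <- as_manifest_path(input[1])
      recs <- load_manifest_recordings(manifest_path, config)
      table <- extract_features(recs, filter_spec = config_filter(config),
                                seg_seconds = config$segment_seconds,
                                n_bins = config$entropy_bins)
      path <- file.path(output, "features.csv")
      write_feature_table(table, path, metadata = meta)
      c(features = path)
    },
    select = {
      need_input()
      table <- read_feature_table(input[1])
      ranking <- rank_features(table, alpha = config$selection_alpha)
      curve <- incremental_feature_evaluation(table, ranking,
                                              config_model(config),
                                              config$test_fraction)
      rank_path <- file.path(output, "ranking.csv")
      curve_path <- file.path(output, "feature_curve.csv")
      write_feature_table(as.data.frame(ranking), rank_path, metadata = meta)
      write_feature_table(as.data.frame(curve), curve_path,
                          metadata = c(meta,
                                       selected = paste(attr(curve, "selected"),
                                                        collapse = "+")))
      c(ranking = rank_path, curve = curve_path)
    },
    train = {
      need_input()
      table <- read_feature_table(input[1])
      split <- split_dataset(table, config$test_fraction, seed = config$seed)
      train_tab <- if (isTRUE(config$balance)) {
        balance_classes(split$train, seed = config$seed)
      } else split$train
      model <- train_classifier(train_tab, config_model(config),
                                features = config_features(config, table))
      path <- file.path(output, "model.json")
      save_model(model, path)
      c(model = path)
    },
    evaluate = {
      need_input()
      if (length(input) < 2L) {
        stop_respscreen("evaluate needs c(features_csv, model_json)",
                        class = "respscreen_io_error")
      }
      table <- read_feature_table(input[1])
      model <- load_model(input[2])
      split <- split_dataset(table, config$test_fraction, seed = config$seed)
      cm <- confusion_matrix(split$test$label,
                             predict_classes(model, split$test),
                             classes = model$classes)
      metrics <- per_class_metrics(cm)
      path <- file.path(output, "metrics.csv")
      out <- metrics$per_class
      out$accuracy <- metrics$accuracy
      write_feature_table(out, path,
                          metadata = c(meta,
                                       macro_sensitivity =
                                         format(metrics$macro["sensitivity"]),
                                       macro_specificity =
                                         format(metrics$macro["specificity"]),
                                       macro_precision =
                                         format(metrics$macro["precision"])))
      c(metrics = path)
    },
    screen = {
      need_input()
      if (length(input) < 2L) {
        stop_respscreen("screen needs c(manifest_or_wav, model_json)",
                        class = "respscreen_io_error")
      }
      model <- load_model(input[2])
      first <- input[1]
      recs <- if (dir.exists(first) || grepl("[.]csv$", first)) {
        load_manifest_recordings(as_manifest_path(first), config)
      } else {
        list(load_recording(first, target_rate = config$sample_rate,
                            subject_id = sub("[.]wav$", "", basename(first))))
      }
      groups <- lapply(recs, function(r) screen_recording(model, r, config))
      names(groups) <- vapply(recs, function(r) {
        if (!is.na(r$subject_id)) r$subject_id else "recording"
      }, character(1))
      report <- screening_report(groups, classes = model$classes)
      path <- file.path(output, "screening.csv")
      write_feature_table(as.data.frame(report), path, metadata = meta)
      c(screening = path)
    })
  invisible(artifacts)
}
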