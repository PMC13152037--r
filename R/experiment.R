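# Full-experiment orchestration: simulate -> preprocess -> featurize ->
# k-fold train -> evaluate -> noise test, from one nested configuration,
# with per-stage seeds fanned out from a single master seed.

#' Default experiment configuration
#'
#' The "paper" preset uses the study protocol (5 folds, 50 epochs, 224 px
#' inputs, 522 samples per class); "smoke" is a fast small-scale variant
#' for pipeline checks (2 folds, 2 epochs, 64 px, 50 per class).
#'
#' @param preset "paper" or "smoke".
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Run output directory.
#' @return Nested configuration list of class `run_config`.
#' @export
default_run_config <- function(preset = c("paper", "smoke"), seed = 1,
                               out_dir = tempfile("coughscope_run_")) {
  preset <- match.arg(preset)
  smoke <- preset == "smoke"
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulation = list(per_class = if (smoke) 50L else 522L, preset = "default"),
    preprocessing = list(rate = 16000, duration_s = 3.0, mu = 0.97,
                         min_keep_s = 0.5, trim = FALSE),
    features = list(frame_len_s = 0.025, hop_s = 0.010, n_fft = 512L,
                    input_size = if (smoke) 64L else 224L),
    model = list(num_classes = 5L, attention_enabled = TRUE,
                 attention_position = "post_sum"),
    training = list(lr = 0.001, epochs = if (smoke) 2L else 50L,
                    batch_size = 8L, step_size = 7L, gamma = 0.1,
                    folds = if (smoke) 2L else 5L),
    evaluation = list(snr_db = c(30, 20, 10))
  ), class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' `read_run_config(write_run_config(cfg, path))` reproduces `cfg`.
#'
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @return `path` (write) or the `run_config` (read).
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- unclass(default_run_config())
  for (sec in names(raw)) {
    if (is.list(base[[sec]]) && is.list(raw[[sec]]))
      base[[sec]] <- modifyList(base[[sec]], raw[[sec]])
    else base[[sec]] <- raw[[sec]]
  }
  base$seed <- as.integer(base$seed)
  base$evaluation$snr_db <- as.numeric(unlist(base$evaluation$snr_db))
  structure(base, class = "run_config")
}

log_stage <- function(stage, seed, t0) {
  message(sprintf("[%s] stage=%s seed=%d elapsed=%.1fs",
                  format(Sys.time(), "%H:%M:%S"), stage, seed,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full experiment from one configuration
#'
#' Executes every stage in order, writing per-fold training histories, the
#' aggregated metrics report, the pooled confusion matrix, the noise
#' robustness table, and a MANIFEST.json of artifact md5 hashes to
#' `cfg$out_dir`. A failing stage aborts with the stage name; artifacts
#' written so far are moved under `failed/`.
#'
#' @param cfg A `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @param verbose Log stage progress.
#' @return The run directory path, invisibly; the aggregated results are in
#'   `<out_dir>/metrics.json` and returned as attribute "results".
#' @export
run_experiment <- function(cfg = default_run_config("smoke"), verbose = TRUE) {
  t0 <- as.numeric(Sys.time())
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  res <- tryCatch({
    stage <- "simulate"
    sim_seed <- stage_seed(cfg$seed, "simulate")
    if (verbose) log_stage(stage, sim_seed, t0)
    specs <- default_class_specs(cfg$simulation$preset)
    corpus <- simulate_corpus(cfg$simulation$per_class, specs, seed = sim_seed,
                              sample_rate = cfg$preprocessing$rate,
                              duration_s = cfg$preprocessing$duration_s)

    stage <- "preprocess"
    if (verbose) log_stage(stage, cfg$seed, t0)
    segments <- list()
    for (i in seq_along(corpus$waveforms)) {
      w <- peak_normalize(corpus$waveforms[[i]])
      segs <- segment_audio(w, cfg$preprocessing$duration_s,
                            cfg$preprocessing$min_keep_s,
                            label = corpus$labels[i],
                            source_id = sprintf("sim%05d", i))
      if (!is.na(cfg$preprocessing$mu))
        segs <- lapply(segs, pre_emphasize, mu = cfg$preprocessing$mu)
      segments <- c(segments, segs)
    }

    stage <- "featurize"
    if (verbose) log_stage(stage, cfg$seed, t0)
    feat <- featurize_segments(segments, size = cfg$features$input_size,
                               frame_len_s = cfg$features$frame_len_s,
                               hop_s = cfg$features$hop_s,
                               n_fft = cfg$features$n_fft)

    stage <- "train"
    train_seed <- stage_seed(cfg$seed, "train")
    if (verbose) log_stage(stage, train_seed, t0)
    tcfg <- train_config(lr = cfg$training$lr, epochs = cfg$training$epochs,
                         batch_size = cfg$training$batch_size,
                         step_size = cfg$training$step_size,
                         gamma = cfg$training$gamma, seed = train_seed)
    ncfg <- network_config(num_classes = cfg$model$num_classes,
                           input_size = cfg$features$input_size,
                           attention_enabled = cfg$model$attention_enabled,
                           attention_position = cfg$model$attention_position)
    cv <- crossval_train(feat$inputs, feat$labels, k = cfg$training$folds,
                         cfg = tcfg, net_cfg = ncfg,
                         fold_seed = stage_seed(cfg$seed, "folds"),
                         verbose = verbose)
    for (f in seq_along(cv$fold_results)) {
      write.csv(cv$fold_results[[f]]$history,
                file.path(out, sprintf("fold%d_history.csv", f)),
                row.names = FALSE)
    }
    save_checkpoint(cv$fold_results[[1]]$model,
                    file.path(out, "fold1_checkpoint.rds"),
                    meta = list(fold = 1, best_epoch = cv$fold_results[[1]]$best_epoch))

    stage <- "evaluate"
    if (verbose) log_stage(stage, cfg$seed, t0)
    write.csv(as.data.frame.matrix(unclass(cv$confusion)),
              file.path(out, "confusion_matrix.csv"))
    write.csv(cv$report$summary, file.path(out, "metrics_summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(
      accuracy = cv$report$pooled$accuracy,
      macro = as.list(cv$report$pooled$macro),
      per_fold_val_acc = vapply(cv$fold_results, `[[`, numeric(1), "best_val_acc"),
      n = cv$report$pooled$n),
      file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA)

    stage <- "noise"
    noise_seed <- stage_seed(cfg$seed, "noise")
    if (verbose) log_stage(stage, noise_seed, t0)
    f1_val <- cv$fold_results[[1]]$val_idx
    noise_tab <- noise_robustness_eval(cv$fold_results[[1]]$model,
                                       segments[f1_val],
                                       snr_db = cfg$evaluation$snr_db,
                                       seed = noise_seed,
                                       input_size = cfg$features$input_size,
                                       frame_len_s = cfg$features$frame_len_s,
                                       hop_s = cfg$features$hop_s,
                                       n_fft = cfg$features$n_fft)
    write.csv(noise_tab, file.path(out, "noise_robustness.csv"), row.names = FALSE)

    write_run_config(cfg, file.path(out, "config.yaml"))
    arts <- setdiff(list.files(out), "MANIFEST.json")
    jsonlite::write_json(
      as.list(setNames(unname(tools::md5sum(file.path(out, arts))), arts)),
      file.path(out, "MANIFEST.json"), auto_unbox = TRUE)
    list(cv = cv, noise = noise_tab, segments_n = length(segments))
  }, error = function(e) {
    failed <- file.path(out, "failed")
    dir.create(failed, showWarnings = FALSE)
    file.rename(setdiff(list.files(out, full.names = TRUE), failed),
                file.path(failed, setdiff(list.files(out), "failed")))
    stopf("experiment stage '%s' failed: %s", stage, conditionMessage(e))
  })
  structure(invisible(out), results = res)
}

#' Compare attention-on vs attention-off training
#'
#' Trains the network twice with identical data, folds and seeds — once
#' with the channel attention modules, once without — and reports mean
#' validation accuracy and macro F1 for each. The direction of the
#' difference is reported, not asserted.
#'
#' @param inputs,labels Featurized dataset as for [crossval_train()].
#' @param k Folds.
#' @param cfg,net_cfg Training and network configuration (attention flag is
#'   overridden per arm).
#' @param fold_seed Fold assignment seed.
#' @return data.frame with one row per arm: attention, mean_val_acc,
#'   macro_f1, accuracy.
#' @export
compare_attention <- function(inputs, labels, k = 2, cfg = train_config(),
                              net_cfg = network_config(), fold_seed = 1) {
  one <- function(flag) {
    nc <- net_cfg
    nc$attention_enabled <- flag
    cv <- crossval_train(inputs, labels, k = k, cfg = cfg, net_cfg = nc,
                         fold_seed = fold_seed)
    data.frame(attention = flag,
               mean_val_acc = mean(vapply(cv$fold_results, `[[`, numeric(1),
                                          "best_val_acc")),
               macro_f1 = unname(cv$report$pooled$macro["f1"]),
               accuracy = cv$report$pooled$accuracy)
  }
  rbind(one(TRUE), one(FALSE))
}
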