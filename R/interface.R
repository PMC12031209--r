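#' Default pipeline configuration
#'
#' One nested list drives the whole pipeline (simulator, preprocessing,
#' model, training); it round-trips through YAML without loss and every CLI
#' run writes the resolved configuration beside its outputs.
#'
#' @return Nested list with blocks \code{simulator}, \code{preprocess},
#'   \code{model}, \code{training} and a master \code{seed}.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulator = list(repeats = 5L, noise_sd = 0.01, drift_rate = 0),
    preprocess = list(loffset = 700L, roffset = 400L, d_threshold = 600L,
                      w = 256L, step_s = 0.5, min_height = 1.3,
                      min_distance = 600L),
    model = list(reduction = 4L, use_attention = TRUE,
                 use_cross_fusion = TRUE, loss = "dynamic",
                 sigma_init = c(1, 1, 1), scale_targets = 100),
    training = list(epochs = 20L, lr = 2e-3, batch_size = 5L, k = 5L)
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config Nested configuration list.
#' @return \code{read_pipeline_config}: the configuration merged over the
#'   defaults; \code{write_pipeline_config}: invisibly, \code{path}.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  for (blk in names(user)) {
    if (is.list(user[[blk]])) {
      for (key in names(user[[blk]])) cfg[[blk]][[key]] <- user[[blk]][[key]]
    } else {
      cfg[[blk]] <- user[[blk]]
    }
  }
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

cfg_preprocess_params <- function(cfg) {
  p <- cfg$preprocess
  preprocess_params(loffset = p$loffset, roffset = p$roffset,
                    d_threshold = p$d_threshold, w = p$w, step_s = p$step_s,
                    min_height = p$min_height, min_distance = p$min_distance)
}

cfg_model_config <- function(cfg) {
  m <- cfg$model
  mrca_config(input_n = as.integer(round(sqrt(cfg$preprocess$w))),
              reduction = m$reduction, use_attention = m$use_attention,
              use_cross_fusion = m$use_cross_fusion, loss = m$loss,
              sigma_init = m$sigma_init, scale_targets = m$scale_targets)
}

cfg_train_config <- function(cfg) {
  tr <- cfg$training
  train_config(epochs = tr$epochs, lr = tr$lr, batch_size = tr$batch_size,
               lr_decay = tr$lr_decay %||% 0.15,
               decay_after = tr$decay_after %||% 0.6)
}

#' Run the full pipeline in memory
#'
#' simulate -> preprocess -> grouped k-fold cross-validation, entirely
#' driven by one configuration and one seed.
#'
#' @param cfg Pipeline configuration (see \code{default_pipeline_config}).
#' @return List with \code{campaign}, \code{dataset} and \code{cv}.
#' @export
run_pipeline <- function(cfg = default_pipeline_config()) {
  camp_cfg <- campaign_config(repeats = cfg$simulator$repeats,
                              noise_sd = cfg$simulator$noise_sd,
                              drift_rate = cfg$simulator$drift_rate)
  campaign <- generate_campaign(camp_cfg, seed = cfg$seed)
  message(sprintf("simulated %d recordings (%d labeled responses)",
                  length(campaign$recordings), nrow(campaign$manifest)))
  dataset <- preprocess_campaign(campaign$recordings, cfg_preprocess_params(cfg))
  message(sprintf("preprocessed %d samples of shape %s",
                  length(dataset$labels),
                  paste(dim(dataset$tensors)[1:3], collapse = "x")))
  cv <- cross_validate(dataset, cfg_model_config(cfg), cfg_train_config(cfg),
                       k = cfg$training$k, seed = cfg$seed)
  list(campaign = campaign, dataset = dataset, cv = cv)
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      flags[[substring(a, 3)]] <- if (i < length(args) &&
                                      !startsWith(args[i + 1], "--")) {
        i <- i + 1
        args[i]
      } else TRUE
    }
    i <- i + 1
  }
  flags
}

cli_load_config <- function(flags) {
  cfg <- if (!is.null(flags$config)) read_pipeline_config(flags$config)
         else default_pipeline_config()
  if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
  cfg
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate} (write recordings + manifest),
#' \code{preprocess} (recordings directory -> dataset archive + label
#' manifest), \code{train}, \code{evaluate} (grouped CV -> metrics JSON),
#' \code{sweep} and \code{ablate}. Shared flags: \code{--config} (YAML),
#' \code{--seed}, \code{--out} (output directory), \code{--in} (input
#' directory). Installed alongside the package as \code{exec/mrcanet}.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success, 2 on usage/configuration
#'   errors), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mrcanet <simulate|preprocess|train|evaluate|sweep|ablate>",
    "[--config cfg.yaml] [--seed N] [--out dir] [--in dir]",
    "[--widths w1,w2,...] [--variants all|name]")
  if (length(args) == 0) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- args[1]
  if (!cmd %in% c("simulate", "preprocess", "train", "evaluate", "sweep",
                  "ablate")) {
    message("unknown command: ", cmd)
    message(usage)
    return(invisible(2L))
  }
  flags <- parse_cli_flags(args[-1])
  status <- tryCatch({
    cfg <- cli_load_config(flags)
    out <- flags$out %||% "."
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    write_pipeline_config(cfg, file.path(out, "resolved_config.yaml"))
    switch(cmd,
      simulate = cli_simulate(cfg, out),
      preprocess = cli_preprocess(cfg, flags$`in` %||% out, out),
      train = cli_train(cfg, flags$`in` %||% out, out),
      evaluate = cli_evaluate(cfg, flags$`in` %||% out, out),
      sweep = cli_sweep(cfg, flags, out),
      ablate = cli_ablate(cfg, flags, out))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cli_simulate <- function(cfg, out) {
  camp_cfg <- campaign_config(repeats = cfg$simulator$repeats,
                              noise_sd = cfg$simulator$noise_sd,
                              drift_rate = cfg$simulator$drift_rate)
  campaign <- generate_campaign(camp_cfg, seed = cfg$seed)
  for (rec in campaign$recordings) write_recording(rec, out)
  jsonlite::write_json(campaign$manifest, file.path(out, "manifest.json"),
                       digits = NA)
  message(sprintf("wrote %d recordings, manifest lists %d responses",
                  length(campaign$recordings), nrow(campaign$manifest)))
}

cli_read_recordings <- function(in_dir) {
  csvs <- list.files(in_dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(csvs) == 0) stopf("no recordings found in '%s'", in_dir)
  lapply(csvs, read_recording)
}

cli_preprocess <- function(cfg, in_dir, out) {
  recs <- cli_read_recordings(in_dir)
  ds <- preprocess_campaign(recs, cfg_preprocess_params(cfg))
  saveRDS(ds, file.path(out, "dataset.rds"))
  labels <- data.frame(index = seq_along(ds$labels),
                       label = as.character(ds$labels),
                       propanol = ds$conc[, "propanol"],
                       ethanol = ds$conc[, "ethanol"],
                       scheme_id = ds$scheme_id,
                       repeat_index = ds$repeat_index)
  jsonlite::write_json(labels, file.path(out, "labels.json"), digits = NA)
  message(sprintf("wrote dataset.rds with %d samples (%s)",
                  length(ds$labels),
                  paste(dim(ds$tensors)[1:3], collapse = "x")))
}

cli_train <- function(cfg, in_dir, out) {
  ds <- readRDS(file.path(in_dir, "dataset.rds"))
  fit <- train_mrca(ds, cfg_model_config(cfg), cfg_train_config(cfg),
                    seed = cfg$seed)
  save_checkpoint(fit, file.path(out, "checkpoint.rds"))
  utils::write.csv(fit$history, file.path(out, "history.csv"),
                   row.names = FALSE)
  message(sprintf("trained %d epochs; final total loss %.4f",
                  nrow(fit$history), fit$history$total[nrow(fit$history)]))
}

metrics_to_json <- function(cv, path) {
  out <- list(
    summary = cv$summary,
    per_fold = lapply(cv$reports, function(r) {
      list(accuracy = r$accuracy, precision = r$precision,
           recall = r$recall, f1 = r$f1, mae = r$mae, r2 = r$r2,
           auc = as.list(r$auc), confusion = unclass(r$confusion))
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
}

cli_evaluate <- function(cfg, in_dir, out) {
  ds <- readRDS(file.path(in_dir, "dataset.rds"))
  cv <- cross_validate(ds, cfg_model_config(cfg), cfg_train_config(cfg),
                       k = cfg$training$k, seed = cfg$seed)
  metrics_to_json(cv, file.path(out, "metrics.json"))
  message(sprintf("cross-validated: accuracy %.4f, R2 %.4f",
                  cv_metric(cv, "accuracy"), cv_metric(cv, "r2")))
}

cli_sweep <- function(cfg, flags, out) {
  recs <- cli_read_recordings(flags$`in` %||% out)
  widths <- if (!is.null(flags$widths))
    as.integer(strsplit(flags$widths, ",")[[1]]) else c(11:17, 19, 21, 23, 25, 27)^2
  tab <- window_length_sweep(recs, widths, cfg_model_config(cfg),
                             cfg_train_config(cfg), cfg_preprocess_params(cfg),
                             k = cfg$training$k, seed = cfg$seed)
  utils::write.csv(tab, file.path(out, "sweep.csv"), row.names = FALSE)
  message(sprintf("swept %d widths", nrow(tab)))
}

cli_ablate <- function(cfg, flags, out) {
  ds <- readRDS(file.path(flags$`in` %||% out, "dataset.rds"))
  variants <- ablation_variants(input_n = as.integer(round(sqrt(cfg$preprocess$w))))
  pick <- flags$variants %||% "all"
  if (pick != "all") {
    if (!pick %in% names(variants)) stopf("unknown variant '%s'", pick)
    variants <- variants[pick]
  }
  results <- lapply(names(variants), function(nm) {
    cv <- cross_validate(ds, variants[[nm]], cfg_train_config(cfg),
                         k = cfg$training$k, seed = cfg$seed)
    data.frame(variant = nm, accuracy = cv_metric(cv, "accuracy"),
               f1 = cv_metric(cv, "f1"), mae = cv_metric(cv, "mae"),
               r2 = cv_metric(cv, "r2"))
  })
  tab <- do.call(rbind, results)
  utils::write.csv(tab, file.path(out, "ablation.csv"), row.names = FALSE)
  message(sprintf("ran %d ablation variants", nrow(tab)))
}
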