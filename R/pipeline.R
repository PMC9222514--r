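# End-to-end orchestration: preprocess -> extract features -> (optionally
# WDO-tune) train DSSAE -> evaluate -> report.

#' Default pipeline configuration
#'
#' Nested list of every pipeline setting with its default. A run's global
#' `seed` fans out deterministically into per-stage seeds (see
#' [stage_seed()]), so stages can be rerun in isolation.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    data = list(source = "synthetic",      # "synthetic" or "directory"
                path = NULL,               # directory / manifest for images
                n_per_class = c(345, 263, 536),
                patch_size = 128, separability = 1, noise_sd = 0.05),
    filtering = list(smoothing = "bilateral", sigma_s = 1.5, sigma_r = 0.1,
                     radius = 3, enhance = "clahe"),
    network = list(input_size = 128, width = 1, tap_point = "gap"),
    classifier = list(hidden_dims = c(256, 128, 64, 32), rho = 0.05,
                      c_s = 1.0, c_w = 1e-4, epochs = 100, batch_size = Inf,
                      learning_rate = 0.01, fine_tune = 0),
    tune = list(enabled = FALSE, population = 20, iterations = 50),
    split = "80/20",
    seed = 1)
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings over [default_config()]; any field name not present
#' in the defaults is a validation error naming the field.
#'
#' @param ... top-level sections (e.g. `data = list(separability = 0.5)`) or
#'   scalar settings (`seed = 7`).
#' @param config optional full configuration list to validate/merge instead.
#' @return validated configuration list.
#' @export
pipeline_config <- function(..., config = NULL) {
  user <- if (is.null(config)) list(...) else config
  merge_validate(default_config(), user, path = "")
}

merge_validate <- function(base, user, path) {
  for (nm in names(user)) {
    full <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(base))
      stop("unknown configuration field: ", full)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration field ", full, " must be a list")
      base[[nm]] <- merge_validate(base[[nm]], user[[nm]], full)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; fields are validated against [default_config()].
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  for (s in c("data", "classifier")) {           # YAML lists -> vectors
    for (f in c("n_per_class", "hidden_dims"))
      if (!is.null(obj[[s]][[f]])) obj[[s]][[f]] <- unlist(obj[[s]][[f]])
  }
  if (!is.null(obj$classifier$batch_size) &&
      identical(obj$classifier$batch_size, "full"))
    obj$classifier$batch_size <- Inf
  pipeline_config(config = obj)
}

load_input_patches <- function(cfg) {
  if (cfg$data$source == "synthetic") {
    generate_images(n_per_class = cfg$data$n_per_class,
                    patch_size = cfg$data$patch_size,
                    separability = cfg$data$separability,
                    noise_sd = cfg$data$noise_sd,
                    seed = stage_seed(cfg$seed, "generate"))
  } else if (cfg$data$source == "directory") {
    if (is.null(cfg$data$path)) stop("data.path required for directory source")
    read_patches(cfg$data$path)
  } else stop("unknown data source: ", cfg$data$source)
}

pipeline_network <- function(cfg, n_classes) {
  build_network(squeezenet_spec(input_size = cfg$network$input_size,
                                in_channels = 1, n_classes = n_classes,
                                width = cfg$network$width),
                seed = stage_seed(cfg$seed, "network"))
}

preprocess_all <- function(patches, cfg) {
  params <- bilateral_params(sigma_s = cfg$filtering$sigma_s,
                             sigma_r = cfg$filtering$sigma_r,
                             radius = cfg$filtering$radius)
  lapply(patches, preprocess_patch, smoothing = cfg$filtering$smoothing,
         params = params, enhance = cfg$filtering$enhance)
}

#' Run the full classification pipeline
#'
#' Generates or loads patches, pre-processes them (bilateral or Gaussian
#' smoothing plus contrast enhancement), extracts frozen convolutional
#' features, trains the stacked sparse autoencoder classifier (optionally
#' with WDO hyperparameter tuning on the training split), and evaluates both
#' splits with the per-class metric suite.
#'
#' The run directory receives: the resolved `config.yaml`, `model.json`, a
#' per-split metrics CSV/Markdown pair and confusion-matrix CSV, the
#' training trace CSV, the WDO history CSV (when tuning), and a
#' machine-readable `summary.json`. Reruns with an identical configuration
#' produce identical artifacts. On failure a `FAILED` marker naming the
#' stage is left in the run directory and the error is rethrown.
#'
#' @param config configuration list from [pipeline_config()] /
#'   [read_pipeline_config()].
#' @param out_dir run directory (created; default: a fresh temporary
#'   directory).
#' @return invisibly, the summary list (with `$dir` the run directory).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  cfg <- pipeline_config(config = config)
  if (is.null(out_dir)) out_dir <- tempfile("run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "configure"
  fail <- function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    yaml::write_yaml(encode_config(cfg), file.path(out_dir, "config.yaml"))

    stage <- "generate"
    patches <- load_input_patches(cfg)
    labels <- vapply(patches, `[[`, "", "label")
    class_names <- sort(unique(labels))

    stage <- "split"
    parts <- split_dataset(labels, split_preset(cfg$split),
                           seed = stage_seed(cfg$seed, "split"))

    stage <- "filter"
    patches <- preprocess_all(patches, cfg)

    stage <- "features"
    net <- pipeline_network(cfg, length(class_names))
    feats <- extract_features(patches, net, cfg$network$tap_point)

    stage <- "train"
    tr <- parts$train; te <- parts$test
    cl <- cfg$classifier
    tuned <- NULL
    if (isTRUE(cfg$tune$enabled)) {
      tuned <- tune_dssae(feats[tr, , drop = FALSE], labels[tr],
                          space = default_search_space(),
                          config = wdo_config(
                            population = cfg$tune$population,
                            iterations = cfg$tune$iterations,
                            seed = stage_seed(cfg$seed, "tune")),
                          hidden_dims = cl$hidden_dims,
                          rho = cl$rho, c_s = cl$c_s, c_w = cl$c_w,
                          fine_tune = cl$fine_tune)
      model <- tuned$model
      utils::write.csv(tuned$history, file.path(out_dir, "wdo_history.csv"),
                       row.names = FALSE)
    } else {
      model <- train_dssae(feats[tr, , drop = FALSE], labels[tr],
                           hidden_dims = cl$hidden_dims, rho = cl$rho,
                           c_s = cl$c_s, c_w = cl$c_w, epochs = cl$epochs,
                           batch_size = cl$batch_size,
                           learning_rate = cl$learning_rate,
                           fine_tune = cl$fine_tune,
                           seed = stage_seed(cfg$seed, "train"))
    }
    save_dssae(model, file.path(out_dir, "model.json"))
    write_trace(model, file.path(out_dir, "training_trace.csv"))

    stage <- "evaluate"
    reports <- list()
    for (sp in c("train", "test")) {
      idx <- parts[[sp]]
      pred <- predict(model, feats[idx, , drop = FALSE])
      cm <- confusion_matrix(labels[idx], pred, class_names)
      utils::write.csv(as.data.frame(unclass(cm)),
                       file.path(out_dir, paste0("confusion_", sp, ".csv")))
      rep <- render_report(cm,
                           csv = file.path(out_dir,
                                           paste0("metrics_", sp, ".csv")),
                           markdown = file.path(out_dir,
                                                paste0("metrics_", sp, ".md")))
      reports[[sp]] <- list(
        error_rate = error_rate(pred, labels[idx]),
        accuracy = 100 - error_rate(pred, labels[idx]),
        n = length(idx),
        macro = as.list(rep$table[rep$table$class == "Average", -1]))
    }

    stage <- "report"
    summary <- list(
      seed = cfg$seed, split = cfg$split,
      classes = class_names,
      n_samples = length(patches),
      train = reports$train, test = reports$test,
      tuned = if (!is.null(tuned)) list(
        best_hyperparameters = tuned$best_hyperparameters,
        best_validation_error = tuned$best_fitness) else NULL)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    summary$dir <- out_dir
    invisible(summary)
  }, error = fail)
}

# YAML-safe encoding of the resolved config (Inf has no YAML scalar)
encode_config <- function(cfg) {
  if (is.numeric(cfg$classifier$batch_size) &&
      !is.finite(cfg$classifier$batch_size))
    cfg$classifier$batch_size <- "full"
  cfg
}

write_trace <- function(model, path) {
  rows <- list()
  for (nm in names(model$trace)) {
    tr <- model$trace[[nm]]
    if (length(tr))
      rows[[nm]] <- data.frame(layer = nm, iteration = seq_along(tr),
                               loss = tr)
  }
  if (length(rows))
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Evaluate a finished run on new patches
#'
#' Re-applies the persisted pre-processing, the seed-rebuilt frozen feature
#' network and the stored classifier to new data, and reports the per-class
#' metric table.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param patches list of labeled [image_patch()] objects (or a directory /
#'   manifest accepted by [read_patches()]).
#' @return list with `predictions`, `confusion` and `report` (full-precision
#'   metric table).
#' @export
evaluate_run <- function(run_dir, patches) {
  cfgf <- file.path(run_dir, "config.yaml")
  if (!file.exists(cfgf)) stop("not a run directory: ", run_dir)
  cfg <- read_pipeline_config(cfgf)
  if (is.character(patches)) patches <- read_patches(patches)
  if (length(patches) == 0) stop("no patches to evaluate")
  model <- load_dssae(file.path(run_dir, "model.json"))
  patches <- preprocess_all(patches, cfg)
  net <- pipeline_network(cfg, length(model$class_names))
  feats <- extract_features(patches, net, cfg$network$tap_point)
  pred <- predict(model, feats)
  labels <- vapply(patches, `[[`, "", "label")
  if (all(is.na(labels)) || all(labels == "NA"))
    return(list(predictions = pred, confusion = NULL, report = NULL))
  cm <- confusion_matrix(labels, pred, model$class_names)
  list(predictions = pred, confusion = cm,
       report = render_report(cm)$table)
}
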