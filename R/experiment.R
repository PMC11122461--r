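#' Run a full estimation experiment
#'
#' Orchestrates the pipeline end-to-end: simulate the capture dataset,
#' split it (identity-disjoint or mixed), optionally quadruple the
#' training side with flips, prepare input tensors (with optional
#' grey-world balancing and pixel-shuffle ablation), build and optionally
#' freeze the model, train it, and evaluate the held-out split with
#' threshold accuracies and LAB error statistics. Every stage draws its
#' randomness from sub-seeds derived from the configuration's master
#' seed, so identical configurations reproduce identical results.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory: when given, the configuration
#'   snapshot, manifest, per-epoch training log and evaluation report are
#'   written there (filenames carry the config hash).
#' @param quiet Suppress per-stage log lines.
#' @return A `monk_experiment` list: `report` (a `monk_eval_report`),
#'   `fit` (a `monk_fit`), `manifest`, `estimates` (the held-out records
#'   with an `estimate` column) and `config`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           quiet = FALSE) {
  if (!inherits(config, "experiment_config")) {
    abort("config must be an experiment_config()")
  }
  hash <- config_hash(config)
  say <- function(stage, ...) {
    if (!quiet) {
      message(sprintf("[monktone:%s seed=%d cfg=%d] %s", stage,
                      config$seed, hash, sprintf(...)))
    }
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  say("simulate", "%d identities x %d conditions x %d rotations",
      config$simulator$n_identities, nrow(lighting_conditions()),
      length(config$simulator$rotations))
  manifest <- run_stage("simulate", build_dataset(
    n_identities = config$simulator$n_identities,
    rotations = config$simulator$rotations,
    seed = derive_seed(config$seed, "simulate"),
    size = config$simulator$size,
    noise_sigma = config$simulator$noise_sigma,
    complexion_sigma = config$simulator$complexion_sigma %||% 0
  ))

  mode <- if (isTRUE(config$ablation$mixed_identities)) "mixed"
          else config$split$mode
  manifest <- run_stage("split", split_identities(
    manifest, train_fraction = config$split$train_fraction, mode = mode,
    seed = derive_seed(config$seed, "split")
  ))
  train_records <- filter(manifest, .data$split == "train")
  val_records <- filter(manifest, .data$split == "val")
  if (isTRUE(config$ablation$augment)) {
    train_records <- augment_flips(train_records)
  }
  say("preprocess", "%d train / %d val records", nrow(train_records),
      nrow(val_records))

  colour_mode <- if (isTRUE(config$ablation$nine_channel)) "RGB_HSV_LAB"
                 else config$input$colour_mode
  spec <- input_tensor_spec(colour_mode, config$input$side)
  shuffle_seed <- derive_seed(config$seed, "shuffle")
  train_data <- run_stage("preprocess", prepare_tensors(
    train_records, spec, grey_world = isTRUE(config$ablation$grey_world),
    shuffle = isTRUE(config$ablation$pixel_shuffle),
    shuffle_seed = shuffle_seed, margin = config$input$crop_margin
  ))
  val_data <- run_stage("preprocess", prepare_tensors(
    val_records, spec, grey_world = isTRUE(config$ablation$grey_world),
    shuffle = isTRUE(config$ablation$pixel_shuffle),
    shuffle_seed = shuffle_seed, margin = config$input$crop_margin
  ))

  arch <- architecture_spec(config$model$profile, spec$channels,
                            config$model$head, side = spec$side,
                            dropout_p = config$train$dropout_p)
  model <- run_stage("build", build_model(
    arch, seed = derive_seed(config$seed, "init")
  ))
  if (config$model$n_frozen_layers > 0) {
    model <- freeze_layers(model, config$model$n_frozen_layers)
  }
  tconfig <- train_config(
    learning_rate = config$train$learning_rate,
    momentum = config$train$momentum,
    batch_size = config$train$batch_size,
    dropout_p = config$train$dropout_p,
    epochs = config$train$epochs,
    loss = if (config$model$head == "regression") "mse" else "cross_entropy",
    seed = derive_seed(config$seed, "train")
  )
  say("train", "%s/%s for %d epochs", config$model$profile,
      config$model$head, tconfig$epochs)
  fit <- run_stage("train", train_model(model, train_data, val_data, tconfig))

  estimates <- val_records
  if (config$model$head == "regression") {
    estimates$estimate <- predict(fit, val_data)
  } else {
    probs <- predict(fit, val_data)
    estimates$estimate <- as.numeric(max.col(probs, ties.method = "first"))
  }
  report <- run_stage("evaluate", eval_report(
    estimates, thresholds = config$evaluation$thresholds
  ))
  say("evaluate", "val accuracy(0.5) = %.2f%%",
      glance(report)$accuracy_0.5 %||% NA_real_)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    prefix <- file.path(out_dir, sprintf("experiment_%d", hash))
    save_config(config, paste0(prefix, "_config.yaml"))
    write_manifest(manifest, paste0(prefix, "_manifest.csv"))
    readr::write_csv(fit$history, paste0(prefix, "_history.csv"))
    readr::write_csv(tidy(report), paste0(prefix, "_report.csv"))
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed,
           report = tidy(report)),
      paste0(prefix, "_report.json"), auto_unbox = TRUE, digits = NA
    )
  }

  structure(list(report = report, fit = fit, manifest = manifest,
                 estimates = estimates, config = config, hash = hash),
            class = "monk_experiment")
}

#' @export
print.monk_experiment <- function(x, ...) {
  cat(sprintf("<monk_experiment> cfg=%d seed=%d\n", x$hash, x$config$seed))
  print(x$report)
  invisible(x)
}

#' Run the four dataset-permutation ablation arms
#'
#' Crosses identity mixing (identity-disjoint vs mixed) with pixel
#' shuffling (intact vs shuffled) and runs one experiment per arm,
#' mirroring the dataset permutations used to establish that facial
#' structure and identity separation both matter.
#'
#' @param config Base [experiment_config()].
#' @param arms Character subset of
#'   `c("non_mixed", "mixed", "non_mixed_shuffled", "mixed_shuffled")`.
#' @param quiet Passed to [run_experiment()].
#' @return A named list of `monk_experiment` results.
#' @export
run_ablation <- function(config = experiment_config(),
                         arms = c("non_mixed", "mixed",
                                  "non_mixed_shuffled", "mixed_shuffled"),
                         quiet = FALSE) {
  arms <- match.arg(arms, several.ok = TRUE)
  out <- list()
  for (arm in arms) {
    cfg <- config
    cfg$ablation$mixed_identities <- grepl("^mixed", arm)
    cfg$ablation$pixel_shuffle <- grepl("shuffled$", arm)
    out[[arm]] <- run_experiment(cfg, quiet = quiet)
  }
  out
}
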