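#' Read and write capture manifests
#'
#' The manifest CSV schema is
#' `image_path,identity_id,true_tone,light_type,intensity_level,rotation,split`;
#' extra columns (rendering parameters, flips) round-trip losslessly and
#' row order is preserved.
#'
#' @param path CSV file path.
#' @return `read_manifest()` returns a `capture_manifest` tibble.
#' @export
read_manifest <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("image_path", "identity_id", "true_tone", "light_type",
                "intensity_level", "rotation", "split")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("manifest is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_rot <- setdiff(unique(df$rotation), head_rotations())
  if (length(bad_rot) > 0) {
    abort(paste0("unknown rotation token(s): ", paste(bad_rot, collapse = ", ")))
  }
  bad_light <- setdiff(unique(df$light_type), lighting_conditions()$light_type)
  if (length(bad_light) > 0) {
    abort(paste0("unknown light_type token(s): ",
                 paste(bad_light, collapse = ", ")))
  }
  structure(df, class = c("capture_manifest", class(df)))
}

#' @rdname read_manifest
#' @param manifest A manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(as_tibble(manifest), path)
  invisible(path)
}

#' Default experiment configuration
#'
#' A nested configuration covering the whole pipeline, with defaults at
#' the full study protocol: 285 identities, 15 lighting conditions, 5
#' rotations; a 65:35 identity-disjoint split; LAB inputs at 224 px into
#' a VGG-16-style regression model trained with SGD (learning rate 1e-5,
#' momentum 0.9, batch size 32, dropout 0.5). Any field may be overridden
#' through `...` by section, e.g.
#' `experiment_config(simulator = list(n_identities = 60))`.
#'
#' @param ... Named sections (`simulator`, `split`, `input`, `model`,
#'   `train`, `evaluation`, `ablation`) whose entries override defaults,
#'   plus optionally `seed`.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(...) {
  defaults <- list(
    seed = 1L,
    simulator = list(
      n_identities = 285L,
      rotations = head_rotations(),
      size = 128L,
      noise_sigma = 2,
      complexion_sigma = 0
    ),
    split = list(train_fraction = 0.65, mode = "non_mixed"),
    input = list(colour_mode = "LAB", side = 224L, crop_margin = 0.1),
    model = list(profile = "vgg16_like", head = "regression",
                 n_frozen_layers = 0L),
    train = list(learning_rate = 1e-5, momentum = 0.9, batch_size = 32L,
                 dropout_p = 0.5, epochs = 50L),
    evaluation = list(thresholds = c(0.5, 1, 2)),
    ablation = list(pixel_shuffle = FALSE, grey_world = FALSE,
                    nine_channel = FALSE, mixed_identities = FALSE,
                    augment = TRUE)
  )
  config <- merge_config(defaults, list(...), path = "")
  validate_config(config)
}

merge_config <- function(defaults, overrides, path = "") {
  if (length(overrides) == 0) return(defaults)
  nms <- names(overrides)
  if (is.null(nms) || any(nms == "")) {
    abort(paste0("config entries must be named (at '", path, "')"))
  }
  for (nm in nms) {
    full <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(defaults)) {
      abort(paste0("unknown config key '", full, "'"))
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(overrides[[nm]])) {
        abort(paste0("config key '", full, "' must be a section"))
      }
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]], full)
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

validate_config <- function(config) {
  s <- config$simulator
  if (s$n_identities < 1) abort("simulator.n_identities must be >= 1")
  if (!all(s$rotations %in% head_rotations())) {
    abort("simulator.rotations contains unknown rotation tokens")
  }
  if (config$split$train_fraction <= 0 || config$split$train_fraction >= 1) {
    abort("split.train_fraction must lie strictly between 0 and 1")
  }
  if (!config$split$mode %in% c("non_mixed", "mixed")) {
    abort("split.mode must be 'non_mixed' or 'mixed'")
  }
  if (!config$input$colour_mode %in% c("LAB", "RGB", "RGB_HSV_LAB")) {
    abort("input.colour_mode must be LAB, RGB or RGB_HSV_LAB")
  }
  if (!config$model$profile %in% c("tiny", "vgg11_like", "vgg16_like")) {
    abort("model.profile must be tiny, vgg11_like or vgg16_like")
  }
  if (!config$model$head %in% c("regression", "classification")) {
    abort("model.head must be regression or classification")
  }
  # reuse the train_config invariants
  do.call(train_config, c(config$train, list(
    loss = if (config$model$head == "regression") "mse" else "cross_entropy",
    seed = config$seed
  )))
  structure(config, class = "experiment_config")
}

#' Load or save an experiment configuration as YAML
#'
#' `load_config()` parses a YAML file, rejects unknown keys by name,
#' applies defaults for everything unspecified, and validates all
#' invariants. An empty file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(experiment_config, raw)
}

#' @rdname load_config
#' @param config An `experiment_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  hash_string(paste(deparse(unclass(config)), collapse = ""))
}
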