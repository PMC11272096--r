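#' Write a dataset to disk
#'
#' Serializes the dataset (samples, splits, manifest) to a single RDS
#' container and writes the manifest as a JSON sidecar
#' (`<path sans ext>.manifest.json`). Volumes are stored in their native
#' in-memory layout (x, y, layer), layer 1 shallowest, in cm^-1; the
#' convention is recorded in the manifest. Read-back is bitwise exact.
#'
#' @param dataset a `dot_dataset`.
#' @param path output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "dot_dataset"))
  dataset$manifest$volume_layout <-
    "array[x, y, layer], layer 1 shallowest, units cm^-1"
  saveRDS(dataset, path)
  jsonlite::write_json(
    dataset$manifest,
    paste0(tools::file_path_sans_ext(path), ".manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#' @param path dataset file path.
#' @return The `dot_dataset`.
#' @export
read_dataset <- function(path) {
  ds <- readRDS(path)
  if (!inherits(ds, "dot_dataset")) stop("not a dot_dataset file")
  ds
}

#' Write / read a reconstruction volume
#'
#' Stores the 3-D volume with its grid shape and layout convention.
#'
#' @param volume 3-D array (x, y, layer) in cm^-1.
#' @param path file path.
#' @return `path` invisibly / the volume array with a `metadata` attribute.
#' @export
write_volume <- function(volume, path) {
  obj <- list(
    volume = as.array(volume),
    metadata = list(
      shape = dim(volume),
      layout = "array[x, y, layer], layer 1 shallowest",
      units = "cm^-1"
    )
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  obj <- readRDS(path)
  structure(obj$volume, metadata = obj$metadata)
}

#' Write / read model weights
#'
#' @param model an `apunet` (optionally with training metadata attached).
#' @param path checkpoint path.
#' @return `path` invisibly / the model.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  readRDS(path)
}

#' Default run configuration
#'
#' The merged configuration tree driving the command-line pipeline, with
#' sections for geometry, physics, reconstruction, dataset generation, the
#' model, training, and metrics. Every run writes its resolved configuration
#' beside its outputs.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    geometry = list(
      lateral_extent = 9, depth_extent = 3.5,
      fine_lateral_spacing = 0.25, coarse_lateral_spacing = 1.5,
      layer_thickness = 0.5
    ),
    physics = list(
      background_mua = 0.04, background_musp = 6,
      refractive_index = 1.4, modulation_frequency_hz = 140.02e6
    ),
    recon = list(
      lambda_scale = 0.05, max_iterations = 100,
      residual_tolerance = 1e-6, nonnegativity = TRUE,
      depth_compensation = 0.4, sensitivity_floor = 0.005
    ),
    dataset = list(
      n_samples = 100, fraction_multi = 0.25, fraction_artifact = 0.4,
      shot_noise_sd = 0.01,
      splits = list(train = 0.8, val = 0.1, test = 0.1),
      preset = "simulation"
    ),
    model = list(
      preset = "small", use_cot = TRUE, final_relu = TRUE
    ),
    training = list(
      learning_rate = 1e-4, epochs = 200, batch_size = 16,
      decay_factor = 0.5, decay_patience = 10, decay_threshold = 0.01,
      alpha = 5, beta = 1, gamma = 0.01, a = 0.98, b = 0.02
    ),
    metrics = list(
      dilate_lateral = 2, dilate_axial = 1, exclude_rel = 0.05
    )
  )
}

#' Load and validate a YAML run configuration
#'
#' Merges the user YAML over [default_config()]; unknown keys are rejected.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return resolved configuration list.
#' @export
load_config <- function(path = NULL) {
  base <- default_config()
  if (is.null(path)) return(base)
  user <- yaml::read_yaml(path)
  check <- function(u, b, prefix = "") {
    bad <- setdiff(names(u), names(b))
    if (length(bad)) {
      stop("unknown configuration key(s): ",
           paste0(prefix, bad, collapse = ", "))
    }
    for (nm in names(u)) {
      if (is.list(u[[nm]]) && is.list(b[[nm]])) {
        check(u[[nm]], b[[nm]], paste0(prefix, nm, "."))
      }
    }
  }
  check(user, base)
  utils::modifyList(base, user)
}

# materialize package objects from a resolved config
.cfg_grid <- function(cfg) do.call(build_grid, cfg$geometry)
.cfg_props <- function(cfg) {
  optical_properties(cfg$physics$background_mua, cfg$physics$background_musp,
                     cfg$physics$refractive_index)
}
.cfg_recon <- function(cfg) {
  recon_config(lambda_scale = cfg$recon$lambda_scale,
               max_iterations = cfg$recon$max_iterations,
               residual_tolerance = cfg$recon$residual_tolerance,
               nonnegativity = cfg$recon$nonnegativity,
               depth_compensation = cfg$recon$depth_compensation,
               sensitivity_floor = cfg$recon$sensitivity_floor)
}
.cfg_model <- function(cfg) {
  f <- if (identical(cfg$model$preset, "small")) {
    apunet_config_small
  } else {
    apunet_config
  }
  f(use_cot = cfg$model$use_cot, final_relu = cfg$model$final_relu)
}
.cfg_train <- function(cfg) {
  t <- cfg$training
  train_config(
    learning_rate = t$learning_rate, epochs = t$epochs,
    batch_size = t$batch_size, decay_factor = t$decay_factor,
    decay_patience = t$decay_patience, decay_threshold = t$decay_threshold,
    weights = loss_weights(t$alpha, t$beta, t$gamma, t$a, t$b),
    seed = cfg$seed
  )
}
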