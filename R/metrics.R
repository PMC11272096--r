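# binary mask dilation by lateral radius r_lat (voxels) and axial radius
# r_ax (layers), via shift-union (box structuring element)
.dilate_mask <- function(mask, r_lat = 2L, r_ax = 1L) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (dx in -r_lat:r_lat) {
    for (dy in -r_lat:r_lat) {
      for (dz in -r_ax:r_ax) {
        xs <- intersect(seq_len(d[1]), seq_len(d[1]) - dx)
        ys <- intersect(seq_len(d[2]), seq_len(d[2]) - dy)
        zs <- intersect(seq_len(d[3]), seq_len(d[3]) - dz)
        out[xs + dx, ys + dy, zs + dz] <-
          out[xs + dx, ys + dy, zs + dz] | mask[xs, ys, zs]
      }
    }
  }
  out
}

#' Lesion / artifact region labels for the image-quality metrics
#'
#' The lesion region is the ground-truth lesion mask dilated by `r_lat`
#' voxels laterally and `r_ax` layers axially (in the clinic the lesion
#' location comes from coregistered ultrasound; in simulation the known mask
#' plays that role, with the dilation absorbing localization slack). The
#' artifact region is its complement.
#'
#' @param lesion_mask logical 3-D array (ground-truth lesion voxels).
#' @param r_lat,r_ax dilation radii (default 2 voxels lateral, 1 layer
#'   axial).
#' @return A `region_labels` list with disjoint logical volumes
#'   `lesion_region` and `artifact_region`.
#' @export
default_regions <- function(lesion_mask, r_lat = 2L, r_ax = 1L) {
  lesion <- .dilate_mask(lesion_mask, r_lat, r_ax)
  structure(list(lesion_region = lesion, artifact_region = !lesion),
            class = "region_labels")
}

#' Artifact contrast
#'
#' Ratio of the maximum map value in the artifact region to the maximum in
#' the lesion region; a lower value indicates better artifact removal. A
#' nonpositive lesion maximum makes the ratio undefined and the sample is
#' reported as excluded (`NA`).
#'
#' @param map 3-D image volume (absorption perturbation, cm^-1; the clinical
#'   analogue is a hemoglobin map — both are max-ratio metrics).
#' @param regions a [default_regions()] result.
#' @return scalar `C_arti`, or `NA` when excluded.
#' @export
metric_artifact_contrast <- function(map, regions) {
  if (!any(regions$lesion_region)) stop("lesion region is empty")
  lesion_max <- max(map[regions$lesion_region])
  if (lesion_max <= 0) return(NA_real_)
  artifact_max <- max(0, map[regions$artifact_region])
  artifact_max / lesion_max
}

#' Depth contrast between lesion layers
#'
#' `C1j`: ratio of the maximum map value in the lesion's j-th occupied depth
#' layer to the maximum in its first (shallowest) occupied layer. A value
#' near 1 means the depth profile is consistent; under-reconstruction of
#' deep layers (the shadowing effect) pushes it below 1. By default maxima
#' are taken within the lesion's (dilated) lateral footprint so background
#' artifacts cannot contaminate the profile; `whole_layer = TRUE` uses full
#' layers. A layer whose masked maximum falls below `exclude_rel` of the
#' sample's global maximum is excluded (`NA`), mirroring the exclusion of
#' cases with exceptionally low signal.
#'
#' @param map 3-D image volume.
#' @param lesion_mask logical 3-D lesion mask (defines the occupied layers).
#' @param layer which deeper lesion layer to compare (2 for C12, 3 for C13).
#' @param whole_layer use whole depth layers instead of the lesion's lateral
#'   footprint.
#' @param exclude_rel relative exclusion threshold (default 0.05).
#' @param footprint_dilate lateral dilation of the footprint, voxels.
#' @return scalar `C1j`, or `NA` when the lesion does not span `layer`
#'   layers or the exclusion rule fires.
#' @export
metric_depth_contrast <- function(map, lesion_mask, layer = 2,
                                  whole_layer = FALSE, exclude_rel = 0.05,
                                  footprint_dilate = 2L) {
  occupied <- which(apply(lesion_mask, 3, any))
  if (length(occupied) < layer) return(NA_real_)
  l1 <- occupied[1]
  lj <- occupied[layer]
  fp <- apply(.dilate_mask(lesion_mask, footprint_dilate, 0L), c(1, 2), any)
  if (whole_layer) {
    m1 <- max(map[, , l1])
    mj <- max(map[, , lj])
  } else {
    m1 <- max(map[, , l1][fp])
    mj <- max(map[, , lj][fp])
  }
  # exclusion threshold referenced to the lesion footprint's own signal, so
  # a remote artifact spike cannot silence the depth profile
  ref <- max(map[array(fp, dim(map))])
  if (ref <= 0 || m1 < exclude_rel * ref || mj < exclude_rel * ref) {
    return(NA_real_)
  }
  mj / m1
}

# metric row for one volume
.metric_row <- function(map, lesion_mask, regions) {
  data.frame(
    c_arti = metric_artifact_contrast(map, regions),
    c12 = metric_depth_contrast(map, lesion_mask, 2),
    c13 = metric_depth_contrast(map, lesion_mask, 3),
    max_value = max(map)
  )
}

#' Paired metric evaluation of a dataset
#'
#' Computes the artifact-contrast and depth-contrast metrics on the input
#' reconstructions, on the model outputs (when a model is given; the
#' identity mapping otherwise), and on the ground truths, with the identical
#' region and exclusion rules in every arm.
#'
#' @param dataset a `dot_dataset` or list of `dot_sample`s.
#' @param model a trained `apunet`, or `NULL` for the identity model.
#' @param split restrict to one split label (e.g. `"test"`); `NULL` uses all
#'   samples.
#' @return A `metrics_report`: `per_sample` (paired rows with an `arm`
#'   column), `aggregates` (mean, sd, n, exclusions per arm and metric).
#' @export
evaluate_dataset <- function(dataset, model = NULL, split = NULL) {
  samples <- if (inherits(dataset, "dot_dataset")) {
    if (!is.null(split)) {
      dataset$samples[dataset$split == split]
    } else {
      dataset$samples
    }
  } else {
    dataset
  }
  if (!length(samples)) stop("empty dataset")
  outputs <- if (is.null(model)) {
    lapply(samples, `[[`, "input_recon")
  } else {
    apunet_enhance(model, samples)
  }
  rows <- vector("list", 3 * length(samples))
  for (i in seq_along(samples)) {
    sm <- samples[[i]]
    regions <- default_regions(sm$lesion_mask)
    arms <- list(input = sm$input_recon, output = outputs[[i]],
                 ground_truth = sm$ground_truth)
    for (a in names(arms)) {
      r <- .metric_row(arms[[a]], sm$lesion_mask, regions)
      r$sample <- i
      r$arm <- a
      r$artifact <- isTRUE(sm$metadata$artifact)
      rows[[3 * (i - 1) + match(a, names(arms))]] <- r
    }
  }
  per_sample <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_sample, per_sample$arm), function(d) {
    do.call(rbind, lapply(c("c_arti", "c12", "c13"), function(mname) {
      v <- d[[mname]]
      data.frame(arm = d$arm[1], metric = mname,
                 mean = mean(v, na.rm = TRUE),
                 sd = stats::sd(v, na.rm = TRUE),
                 n = sum(!is.na(v)), n_excluded = sum(is.na(v)))
    }))
  }))
  rownames(agg) <- NULL
  structure(list(per_sample = per_sample, aggregates = agg,
                 n_samples = length(samples)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics report over %d samples:\n", x$n_samples))
  print(x$aggregates, row.names = FALSE)
  invisible(x)
}

#' Attention-ablation comparison harness
#'
#' Trains the full model and the attention-ablated model under identical
#' seeds, data and schedule, then evaluates both on the test split. The
#' comparison axis is the paired per-sample metrics and their variances
#' across four arms: input, full-model output, ablated-model output, and
#' ground truth.
#'
#' @param dataset a `dot_dataset` with train/val/test splits.
#' @param model_config an [apunet_config()] shared by both arms.
#' @param training a [train_config()] shared by both arms.
#' @param seed initialization seed shared by both arms.
#' @return An `ablation_report`: `full` and `ablated` metric reports, a
#'   combined `variance_table`, both training logs, and the shared seed.
#' @export
run_ablation <- function(dataset, model_config = apunet_config_small(),
                         training = train_config(), seed = 1L) {
  full <- build_apunet(model_config, seed)
  ablated <- build_ablated_model(model_config, seed)
  fit_full <- train_apunet(full, dataset, training)
  fit_abl <- train_apunet(ablated, dataset, training)
  test_split <- if (any(dataset$split == "test")) "test" else NULL
  rep_full <- evaluate_dataset(dataset, fit_full$model, split = test_split)
  rep_abl <- evaluate_dataset(dataset, fit_abl$model, split = test_split)

  agg_f <- rep_full$aggregates
  agg_a <- rep_abl$aggregates
  arms <- rbind(
    cbind(agg_f[agg_f$arm %in% c("input", "ground_truth"), ], model = "-"),
    cbind(agg_f[agg_f$arm == "output", ], model = "full"),
    cbind(agg_a[agg_a$arm == "output", ], model = "no_attention")
  )
  arms$variance <- arms$sd^2
  structure(
    list(full = rep_full, ablated = rep_abl, variance_table = arms,
         log_full = fit_full$log, log_ablated = fit_abl$log,
         seed = as.integer(seed),
         parameters = c(full = count_parameters(fit_full$model),
                        ablated = count_parameters(fit_abl$model))),
    class = "ablation_report"
  )
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf("Ablation report (seed %d): full %d params, no-attention %d params\n",
              x$seed, x$parameters["full"], x$parameters["ablated"]))
  print(x$variance_table[, c("model", "arm", "metric", "mean", "sd",
                             "variance", "n")], row.names = FALSE)
  invisible(x)
}
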