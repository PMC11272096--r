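#' Default simulation parameter ranges
#'
#' The uniform sampling ranges for synthetic single/multi-target breast
#' phantoms: target size 1.0-4.0 cm, target center depth 0.8-3.5 cm, target
#' absorption 0.1-0.3 cm^-1, target reduced scattering 4.0-8.0 cm^-1,
#' background absorption 0.02-0.06 cm^-1, background reduced scattering
#' 4.0-8.0 cm^-1. Lateral target positions are kept within +/- 1.5 cm of the
#' probe center (lesions are centered under the probe by ultrasound guidance).
#'
#' @return Named list of ranges used by [sample_target_spec()] and
#'   [generate_dataset()].
#' @export
sim_parameter_ranges <- function() {
  list(
    size = c(1.0, 4.0),
    depth = c(0.8, 3.5),
    mua = c(0.1, 0.3),
    musp = c(4.0, 8.0),
    background_mua = c(0.02, 0.06),
    background_musp = c(4.0, 8.0),
    lateral = c(-1.5, 1.5),
    shapes = c("sphere", "ellipsoid", "cube", "two_hemisphere_ball",
               "extruded_glyph")
  )
}

#' Phantom-bench parameter preset
#'
#' Mimics the resin/silicone phantom bench: discrete target absorptions of
#' 0.23 cm^-1 (high contrast) and 0.11 cm^-1 (low contrast) in a 0.02 cm^-1,
#' musp 6 cm^-1 intralipid background, target sizes 1-3 cm at depths
#' 1.0-3.5 cm.
#'
#' @return Named list of ranges in the same format as
#'   [sim_parameter_ranges()], with `mua_choices` replacing the continuous
#'   `mua` range.
#' @export
phantom_parameter_ranges <- function() {
  r <- sim_parameter_ranges()
  r$size <- c(1.0, 3.0)
  r$depth <- c(1.0, 3.5)
  r$mua <- NULL
  r$mua_choices <- c(0.11, 0.23)
  r$musp <- c(6.0, 6.0)
  r$background_mua <- c(0.02, 0.02)
  r$background_musp <- c(6.0, 6.0)
  r$shapes <- c("sphere", "cube")
  r
}

#' Target (inclusion) specification
#'
#' @param shape one of `"sphere"`, `"ellipsoid"`, `"cube"`,
#'   `"two_hemisphere_ball"`, `"extruded_glyph"`.
#' @param center 3-D center in cm (z = depth below the probe face).
#' @param size principal diameters in cm (length 1 is recycled to 3; for the
#'   extruded glyph, `size[1:2]` is the lateral extent and `size[3]` the
#'   extrusion depth span).
#' @param mua_target target absorption, cm^-1.
#' @param musp_target target reduced scattering, cm^-1.
#' @param glyph for `shape = "extruded_glyph"`: `"star"`, `"T"`, `"L"` or
#'   `"U"`.
#' @return A `target_spec`.
#' @export
target_spec <- function(shape, center, size, mua_target, musp_target = 6,
                        glyph = "star") {
  shape <- match.arg(shape, sim_parameter_ranges()$shapes)
  size <- rep_len(as.numeric(size), 3)
  center <- as.numeric(center)
  stopifnot(length(center) == 3)
  if (any(size < 0.1)) stop("degenerate target size")
  if (mua_target <= 0) stop("mua_target must be > 0")
  structure(
    list(shape = shape, center = center, size = size,
         mua_target = mua_target, musp_target = musp_target, glyph = glyph),
    class = "target_spec"
  )
}

# point-in-glyph test on lateral coordinates normalized to [-1, 1]
.glyph_mask <- function(u, v, glyph) {
  switch(glyph,
    star = {
      # 5-point star polygon, even-odd rule
      ang <- pi / 2 + 2 * pi * (0:9) / 10
      rad <- rep(c(1, 0.42), 5)
      px <- rad * cos(ang); py <- rad * sin(ang)
      inside <- logical(length(u))
      j <- 10
      for (i in 1:10) {
        crosses <- ((py[i] > v) != (py[j] > v)) &
          (u < (px[j] - px[i]) * (v - py[i]) / (py[j] - py[i]) + px[i])
        inside <- xor(inside, crosses)
        j <- i
      }
      inside
    },
    T = (abs(u) <= 1 & v >= 0.5 & v <= 1) | (abs(u) <= 0.25 & v >= -1 & v <= 0.5),
    L = (u >= -1 & u <= -0.5 & abs(v) <= 1) | (v >= -1 & v <= -0.5 & abs(u) <= 1),
    U = (abs(u) <= 1 & v <= -0.5 & v >= -1) |
      (u >= -1 & u <= -0.5 & abs(v) <= 1) | (u <= 1 & u >= 0.5 & abs(v) <= 1),
    stop("unknown glyph: ", glyph)
  )
}

# logical membership of points (n x 3) in the target shape
.target_membership <- function(spec, pts) {
  dx <- pts[, 1] - spec$center[1]
  dy <- pts[, 2] - spec$center[2]
  dz <- pts[, 3] - spec$center[3]
  a <- spec$size / 2
  switch(spec$shape,
    sphere = (dx^2 + dy^2 + dz^2) <= a[1]^2,
    ellipsoid = (dx / a[1])^2 + (dy / a[2])^2 + (dz / a[3])^2 <= 1,
    cube = abs(dx) <= a[1] & abs(dy) <= a[2] & abs(dz) <= a[3],
    two_hemisphere_ball = {
      # upper half-ball of radius a joined to a smaller lower half-ball
      r2 <- dx^2 + dy^2 + dz^2
      (dz <= 0 & r2 <= a[1]^2) | (dz > 0 & r2 <= (0.7 * a[1])^2)
    },
    extruded_glyph = {
      lat <- .glyph_mask(dx / a[1], dy / a[2], spec$glyph)
      lat & abs(dz) <= a[3]
    }
  )
}

#' Rasterize a target onto the fine voxel grid
#'
#' Voxels whose centers fall inside the shape receive
#' `dmua = mua_target - background_mua`; glyph shapes are 2-D masks extruded
#' over the target's depth span.
#'
#' @param spec a [target_spec()].
#' @param grid an `imaging_grid`.
#' @param background_mua background absorption, cm^-1.
#' @return list with `ground_truth` (3-D `dmua` array, cm^-1) and
#'   `lesion_mask` (logical 3-D array).
#' @export
rasterize_target <- function(spec, grid, background_mua) {
  top <- spec$center[3] - spec$size[3] / 2
  if (top < -1e-9) stop("target extends above the tissue surface z = 0")
  vc <- voxel_centers(grid)
  inside <- .target_membership(spec, vc)
  dims <- c(grid$nx, grid$ny, grid$nz)
  mask <- array(inside, dims)
  gt <- array(0, dims)
  gt[mask] <- spec$mua_target - background_mua
  list(ground_truth = gt, lesion_mask = mask)
}

#' Draw a random target specification
#'
#' Uniform draws within the configured parameter ranges; deterministic given
#' the seed. The depth draw is constrained so the target's top stays below
#' the tissue surface.
#'
#' @param seed integer RNG seed.
#' @param ranges parameter ranges as from [sim_parameter_ranges()] (must stay
#'   within those defaults).
#' @param grid the `imaging_grid` the target must fit (for validation).
#' @return A `target_spec`.
#' @export
sample_target_spec <- function(seed, ranges = sim_parameter_ranges(),
                               grid = build_grid()) {
  dflt <- sim_parameter_ranges()
  for (nm in c("size", "depth", "musp")) {
    if (ranges[[nm]][1] < dflt[[nm]][1] - 1e-9 ||
        ranges[[nm]][2] > dflt[[nm]][2] + 1e-9) {
      stop("range '", nm, "' outside the supported simulation ranges")
    }
  }
  if (ranges$depth[2] > grid$depth_extent + 1e-9 ||
      max(abs(ranges$lateral)) > grid$lateral_extent / 2) {
    stop("sampling range outside the grid")
  }
  .with_seed(seed, {
    shape <- sample(ranges$shapes, 1)
    d1 <- stats::runif(1, ranges$size[1], ranges$size[2])
    size <- switch(shape,
      ellipsoid = c(d1,
                    stats::runif(1, ranges$size[1], ranges$size[2]),
                    stats::runif(1, ranges$size[1], min(2, ranges$size[2]))),
      extruded_glyph = c(d1, d1, stats::runif(1, 0.5, 2)),
      c(d1, d1, d1)
    )
    depth_lo <- max(ranges$depth[1], size[3] / 2 + 0.05)
    depth <- stats::runif(1, depth_lo, max(depth_lo, ranges$depth[2]))
    mua <- if (!is.null(ranges$mua_choices)) {
      sample(ranges$mua_choices, 1)
    } else {
      stats::runif(1, ranges$mua[1], ranges$mua[2])
    }
    target_spec(
      shape = shape,
      center = c(stats::runif(2, ranges$lateral[1], ranges$lateral[2]), depth),
      size = size,
      mua_target = mua,
      musp_target = stats::runif(1, ranges$musp[1], ranges$musp[2]),
      glyph = sample(c("star", "T", "L", "U"), 1)
    )
  })
}

#' Generate one training sample
#'
#' Composes the full physics pipeline for one phantom: rasterize the
#' target(s), build a dual mesh centered at the (jittered) lesion location,
#' synthesize the clean Born perturbation on the mesh, corrupt it with the
#' degradation spec, reconstruct with the regularized conjugate-gradient
#' solver, and package everything as a training tuple. The clean perturbation
#' is stored as the bottleneck regression target. Shallow targets (top at or
#' above 1 cm depth) additionally receive surface hot-spot contamination in
#' the input reconstruction near the closest source fibers, emulating the
#' source-artifact degradation mode of shallow lesions.
#'
#' @param specs a [target_spec()] or list of them (multi-target sample).
#' @param probe a `probe_geometry`.
#' @param grid an `imaging_grid`.
#' @param props background [optical_properties()].
#' @param degradation optional [degradation_spec()]; `NULL` means clean data.
#' @param config a [recon_config()].
#' @param seed integer seed controlling ROI jitter and hot-spot placement.
#' @param roi_jitter lateral jitter (cm) of the mesh center around the true
#'   target centroid, mimicking ultrasound localization error.
#' @param source_hotspots if `TRUE` (default), inject surface hot spots for
#'   shallow targets.
#' @return A `dot_sample`: `ground_truth`, `input_recon`, `fine_mesh_mask`,
#'   `lesion_mask` (3-D arrays), `perturbation` (clean complex vector) and
#'   `metadata`.
#' @export
generate_sample <- function(specs, probe, grid, props, degradation = NULL,
                            config = recon_config(), seed = 1L,
                            roi_jitter = 0.5, source_hotspots = TRUE) {
  if (inherits(specs, "target_spec")) specs <- list(specs)
  dims <- c(grid$nx, grid$ny, grid$nz)
  gt <- array(0, dims)
  lesion <- array(FALSE, dims)
  for (sp in specs) {
    ras <- rasterize_target(sp, grid, props$mua)
    gt <- gt + ras$ground_truth
    lesion <- lesion | ras$lesion_mask
  }

  centers <- t(vapply(specs, `[[`, numeric(3), "center"))
  centroid <- colMeans(centers)
  half <- grid$lateral_extent / 2
  seeds <- .derive_seeds(seed, 3)
  jit <- .with_seed(seeds[1], stats::runif(2, -roi_jitter, roi_jitter))
  roi_center <- pmin(pmax(centroid[1:2] + jit, -half + 0.25), half - 0.25)
  spread <- max(sqrt((centers[, 1] - roi_center[1])^2 +
                       (centers[, 2] - roi_center[2])^2) +
                  vapply(specs, function(s) max(s$size[1:2]) / 2, 0))
  roi_halfwidth <- min(max(spread + 0.5, 1.0), 3.0)

  mesh <- make_dual_mesh(grid, roi_center, roi_halfwidth)
  W <- build_weight_matrix(probe, mesh, grid, props)
  usc_clean <- forward_perturbation(W, voxels_to_cells(mesh, gt, "mean"))
  usc <- if (is.null(degradation)) {
    usc_clean
  } else {
    apply_degradation(usc_clean, degradation, W)
  }
  recon <- cgd_solve(W, usc, config)
  input_recon <- array(as.numeric(recon), dims)
  fine_mask <- array(mesh$cell_assignment <= mesh$n_fine, dims)

  top_depth <- min(centers[, 3] - vapply(specs, function(s) s$size[3] / 2, 0))
  hotspots <- isTRUE(source_hotspots) && top_depth <= 1.0
  if (hotspots) {
    input_recon <- .with_seed(seeds[2], {
      .add_source_hotspots(input_recon, probe, grid)
    })
  }

  structure(
    list(
      ground_truth = gt,
      input_recon = input_recon,
      fine_mesh_mask = fine_mask,
      lesion_mask = lesion,
      perturbation = usc_clean,
      metadata = list(
        seed = as.integer(seed),
        shapes = vapply(specs, `[[`, "", "shape"),
        n_targets = length(specs),
        center_depth = centers[, 3],
        top_depth = top_depth,
        background_mua = props$mua, background_musp = props$musp,
        roi_center = roi_center, roi_halfwidth = roi_halfwidth,
        lambda = attr(recon, "lambda"),
        artifact = !is.null(degradation) || hotspots,
        hotspots = hotspots
      )
    ),
    class = "dot_sample"
  )
}

# Gaussian surface hot spots under 2-3 source fibers (source-artifact mode
# of shallow lesions); amplitudes relative to the reconstruction maximum
.add_source_hotspots <- function(vol, probe, grid, n_spots = NULL) {
  n_spots <- n_spots %||% sample(2:3, 1)
  amp0 <- max(vol)
  if (amp0 <= 0) amp0 <- 0.05
  src <- probe$source_positions
  pick <- order(src[, 1]^2 + src[, 2]^2)[seq_len(n_spots)]
  lat_x <- matrix(grid$xs, grid$nx, grid$ny)
  lat_y <- matrix(grid$ys, grid$nx, grid$ny, byrow = TRUE)
  for (i in pick) {
    sx <- pmin(pmax(src[i, 1], -grid$lateral_extent / 2),
               grid$lateral_extent / 2)
    sy <- pmin(pmax(src[i, 2], -grid$lateral_extent / 2),
               grid$lateral_extent / 2)
    bump <- exp(-((lat_x - sx)^2 + (lat_y - sy)^2) / (2 * 0.4^2))
    a <- amp0 * stats::runif(1, 0.4, 0.9)
    vol[, , 1] <- vol[, , 1] + a * bump
    vol[, , 2] <- vol[, , 2] + 0.5 * a * bump
  }
  vol
}

#' @export
print.dot_sample <- function(x, ...) {
  cat(sprintf(
    "DOT sample: %d target(s) [%s], top depth %.2f cm, artifact=%s\n",
    x$metadata$n_targets, paste(x$metadata$shapes, collapse = ", "),
    x$metadata$top_depth, x$metadata$artifact
  ))
  invisible(x)
}

# random degradation spec for dataset generation
.random_degradation <- function(seed, probe, background_mua,
                                shot_noise_sd = 0.01, artifact = FALSE) {
  .with_seed(seed, {
    spec <- degradation_spec(shot_noise_sd = shot_noise_sd,
                             seed = .derive_seeds(seed, 1))
    if (artifact) {
      mode <- sample(c("coupling", "heterogeneity", "both"), 1)
      if (mode %in% c("coupling", "both")) {
        ns <- nrow(probe$source_positions)
        nd <- nrow(probe$detector_positions)
        gs <- rep(1 + 0i, ns); gd <- rep(1 + 0i, nd)
        bad <- sample(ns + nd, sample(1:2, 1))
        for (b in bad) {
          g <- stats::runif(1, 0.3, 1.7) *
            exp(1i * stats::runif(1, -pi / 9, pi / 9))
          if (b <= ns) gs[b] <- g else gd[b - ns] <- g
        }
        spec$source_gains <- gs
        spec$detector_gains <- gd
      }
      if (mode %in% c("heterogeneity", "both")) {
        n_blobs <- sample(1:3, 1)
        spec$heterogeneity_blobs <- lapply(seq_len(n_blobs), function(i) {
          list(
            center = c(stats::runif(2, -3, 3), stats::runif(1, 0.5, 2.5)),
            radius = stats::runif(1, 0.4, 1.0),
            dmua = stats::runif(1, 0.25, 0.5) * background_mua *
              sample(c(-1, 1), 1)
          )
        })
      }
    }
    spec
  })
}

#' Generate a full synthetic dataset
#'
#' Draws `n` samples from the configured parameter ranges, a configurable
#' fraction of which carry measurement artifacts (coupling errors and/or
#' heterogeneity clutter) and a configurable fraction of which contain 2-3
#' non-overlapping targets (the multi-target corpus used for pre-training).
#' Background optical properties are redrawn per sample. Samples are labeled
#' with disjoint train/val/test splits.
#'
#' @param n number of samples (>= 1).
#' @param splits named proportions `c(train = , val = , test = )`.
#' @param config list overriding any of: `grid`, `probe`, `ranges`,
#'   `recon` (a `recon_config`), `fraction_multi` (default 0.25),
#'   `fraction_artifact` (default 0.4), `shot_noise_sd` (default 0.01),
#'   `source_hotspots` (default TRUE), `seed` (default 1).
#' @return A `dot_dataset`: list of `dot_sample`s, a `split` factor, and a
#'   manifest.
#' @export
generate_dataset <- function(n, splits = c(train = 0.8, val = 0.1, test = 0.1),
                             config = list()) {
  if (n < 1) stop("n must be >= 1")
  cfg <- utils::modifyList(
    list(grid = build_grid(), probe = build_default_probe(),
         ranges = sim_parameter_ranges(), recon = recon_config(),
         fraction_multi = 0.25, fraction_artifact = 0.4,
         shot_noise_sd = 0.01, source_hotspots = TRUE, seed = 1L),
    config
  )
  seeds <- .derive_seeds(cfg$seed, 4 * n)
  s_spec <- seeds[seq_len(n)]
  s_deg <- seeds[n + seq_len(n)]
  s_pipe <- seeds[2 * n + seq_len(n)]
  s_misc <- seeds[3 * n + seq_len(n)]
  r <- cfg$ranges

  samples <- vector("list", n)
  for (i in seq_len(n)) {
    draws <- .with_seed(s_misc[i], stats::runif(4))
    props <- optical_properties(
      mua = r$background_mua[1] +
        draws[1] * diff(r$background_mua),
      musp = r$background_musp[1] +
        draws[2] * diff(r$background_musp)
    )
    multi <- draws[3] < cfg$fraction_multi
    artifact <- draws[4] < cfg$fraction_artifact
    n_targets <- if (multi) {
      if (draws[3] < cfg$fraction_multi / 2) 3L else 2L
    } else {
      1L
    }
    specs <- .draw_target_set(s_spec[i], r, cfg$grid, props,
                              n_targets = n_targets)
    deg <- .random_degradation(s_deg[i], cfg$probe, props$mua,
                               shot_noise_sd = cfg$shot_noise_sd,
                               artifact = artifact)
    samples[[i]] <- generate_sample(
      specs, cfg$probe, cfg$grid, props,
      degradation = deg, config = cfg$recon, seed = s_pipe[i],
      source_hotspots = cfg$source_hotspots
    )
    samples[[i]]$metadata$artifact <- artifact || samples[[i]]$metadata$hotspots
  }

  split <- .with_seed(cfg$seed, {
    k <- round(n * splits / sum(splits))
    k[1] <- n - sum(k[-1])
    sample(rep(names(splits), times = pmax(k, 0))[seq_len(n)])
  })
  manifest <- list(
    n_samples = n,
    parameter_ranges = r[setdiff(names(r), "shapes")],
    shapes = r$shapes,
    global_seed = cfg$seed,
    splits = as.list(table(split)),
    fraction_multi = cfg$fraction_multi,
    fraction_artifact = cfg$fraction_artifact,
    generator_version = "apunet-0.1.0"
  )
  structure(list(samples = samples, split = split, manifest = manifest),
            class = "dot_dataset")
}

# draw n_targets non-overlapping target specs
.draw_target_set <- function(seed, ranges, grid, props, n_targets = 1L) {
  sds <- .derive_seeds(seed, 8 * n_targets)
  specs <- list()
  si <- 1
  for (t in seq_len(n_targets)) {
    for (try in 1:8) {
      sp <- sample_target_spec(sds[si], ranges, grid)
      si <- si + 1
      if (sp$mua_target <= props$mua) next
      ok <- all(vapply(specs, function(o) {
        sqrt(sum((o$center[1:2] - sp$center[1:2])^2)) >
          0.6 * (max(o$size[1:2]) + max(sp$size[1:2])) / 2
      }, TRUE))
      if (ok) { specs[[t]] <- sp; break }
    }
    if (length(specs) < t) specs[[t]] <- sp # accept overlap after max tries
  }
  specs
}

#' @export
print.dot_dataset <- function(x, ...) {
  cat(sprintf("DOT dataset: %d samples (%s)\n", length(x$samples),
              paste(names(table(x$split)), table(x$split),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
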