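#' Probe geometry: optode layout and modulation frequency
#'
#' Constructs the hand-held probe description used to define the measurement
#' operator: source fiber positions, detector fiber positions (both on the
#' probe face, the z = 0 plane), and the RF modulation frequency of the laser
#' diodes. Coordinates are in cm, right-handed, with z >= 0 pointing into the
#' tissue and the origin at the probe center.
#'
#' @param source_positions numeric matrix (n_src x 3) of optode coordinates in
#'   cm; all z-coordinates must be 0.
#' @param detector_positions numeric matrix (n_det x 3), same convention.
#' @param modulation_frequency modulation frequency in Hz (> 0).
#' @return An object of class `probe_geometry`.
#' @seealso [build_default_probe()]
#' @export
probe_geometry <- function(source_positions, detector_positions,
                           modulation_frequency = 140.02e6) {
  source_positions <- as.matrix(source_positions)
  detector_positions <- as.matrix(detector_positions)
  stopifnot(ncol(source_positions) == 3, ncol(detector_positions) == 3)
  if (modulation_frequency <= 0) stop("modulation_frequency must be > 0")
  if (any(abs(source_positions[, 3]) > 1e-12) ||
      any(abs(detector_positions[, 3]) > 1e-12)) {
    stop("all optodes must lie on the probe plane z = 0")
  }
  all_pos <- rbind(source_positions, detector_positions)
  d <- as.matrix(stats::dist(all_pos))
  diag(d) <- Inf
  if (min(d) < 1e-9) stop("two optodes coincide")
  structure(
    list(
      source_positions = source_positions,
      detector_positions = detector_positions,
      modulation_frequency = modulation_frequency
    ),
    class = "probe_geometry"
  )
}

#' Default 9-source / 14-detector probe layout
#'
#' The default layout places the 9 source fibers and 14 detector fibers on two
#' pairs of rectangular arcs flanking a central 1 x 4 cm slot that houses the
#' coregistered ultrasound transducer. All optodes fit inside a 9 cm aperture
#' and the modulation frequency is 140.02 MHz. Exact fiber coordinates are a
#' frozen package default (probes differ between systems); any layout can be
#' supplied through [probe_geometry()].
#'
#' @return A `probe_geometry` with 9 sources and 14 detectors (126
#'   source-detector pairs).
#' @examples
#' p <- build_default_probe()
#' nrow(p$source_positions)    # 9
#' nrow(p$detector_positions)  # 14
#' @export
build_default_probe <- function() {
  # sources and detectors interleaved on both sides of the slot so the
  # aggregate sensitivity stays laterally balanced
  src <- rbind(
    cbind(c(-3, -1.5, 0, 1.5, 3), -1.2, 0),
    cbind(c(-2.25, -0.75, 0.75, 2.25), 2.2, 0)
  )
  det <- rbind(
    cbind(seq(-3, 3, by = 1), 1.2, 0),
    cbind(seq(-3, 3, by = 1), -2.2, 0)
  )
  probe_geometry(src, det, modulation_frequency = 140.02e6)
}

#' Number of source-detector measurements of a probe
#' @param probe a `probe_geometry`.
#' @return integer, n_src * n_det.
#' @export
n_measurements <- function(probe) {
  nrow(probe$source_positions) * nrow(probe$detector_positions)
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf(
    "DOT probe: %d sources, %d detectors (%d pairs), modulation %.2f MHz\n",
    nrow(x$source_positions), nrow(x$detector_positions),
    n_measurements(x), x$modulation_frequency / 1e6
  ))
  invisible(x)
}

#' Reconstruction voxel grid
#'
#' Builds the imaging grid under the probe: a `lateral_extent` x
#' `lateral_extent` x `depth_extent` cm volume discretized into fine lateral
#' voxels of `fine_lateral_spacing` cm and depth layers of `layer_thickness`
#' cm. Layer 1 is the shallowest. The coarse lateral spacing is carried along
#' for the dual-mesh partition of [make_dual_mesh()].
#'
#' Defaults give the 9 x 9 x 3.5 cm grid with 36 x 36 lateral fine voxels and
#' 7 depth layers (0.25 x 0.25 x 0.5 cm fine voxels, 1.5 x 1.5 x 0.5 cm coarse
#' blocks).
#'
#' @param lateral_extent lateral size in cm (x and y).
#' @param depth_extent depth size in cm.
#' @param fine_lateral_spacing fine voxel lateral size, cm.
#' @param coarse_lateral_spacing coarse block lateral size, cm.
#' @param layer_thickness depth layer thickness, cm.
#' @return An `imaging_grid` with voxel center coordinates.
#' @export
build_grid <- function(lateral_extent = 9, depth_extent = 3.5,
                       fine_lateral_spacing = 0.25,
                       coarse_lateral_spacing = 1.5,
                       layer_thickness = 0.5) {
  sp <- c(fine_lateral_spacing, coarse_lateral_spacing, layer_thickness)
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stop("grid spacings must be positive")
  }
  n_lat <- round(lateral_extent / fine_lateral_spacing)
  n_lay <- round(depth_extent / layer_thickness)
  if (abs(n_lat * fine_lateral_spacing - lateral_extent) > 1e-8 ||
      abs(n_lay * layer_thickness - depth_extent) > 1e-8) {
    stop("spacings must divide the grid extents")
  }
  half <- lateral_extent / 2
  xs <- -half + fine_lateral_spacing * (seq_len(n_lat) - 0.5)
  zs <- layer_thickness * (seq_len(n_lay) - 0.5)
  structure(
    list(
      lateral_extent = lateral_extent, depth_extent = depth_extent,
      fine_lateral_spacing = fine_lateral_spacing,
      coarse_lateral_spacing = coarse_lateral_spacing,
      layer_thickness = layer_thickness,
      nx = n_lat, ny = n_lat, nz = n_lay,
      xs = xs, ys = xs, zs = zs
    ),
    class = "imaging_grid"
  )
}

#' @export
print.imaging_grid <- function(x, ...) {
  cat(sprintf(
    "Imaging grid: %g x %g x %g cm, %d x %d x %d fine voxels\n",
    x$lateral_extent, x$lateral_extent, x$depth_extent, x$nx, x$ny, x$nz
  ))
  invisible(x)
}

#' All voxel centers of a grid
#'
#' @param grid an `imaging_grid`.
#' @return numeric matrix (nx*ny*nz x 3); voxel index runs x fastest, then y,
#'   then depth layer (matching `array(dim = c(nx, ny, nz))` linearization).
#' @export
voxel_centers <- function(grid) {
  cbind(
    rep(grid$xs, times = grid$ny * grid$nz),
    rep(rep(grid$ys, each = grid$nx), times = grid$nz),
    rep(grid$zs, each = grid$nx * grid$ny)
  )
}

#' Fine voxel volume in cm^3
#' @param grid an `imaging_grid`.
#' @export
voxel_volume <- function(grid) {
  grid$fine_lateral_spacing^2 * grid$layer_thickness
}

#' Dual fine/coarse mesh partition
#'
#' Partitions the voxel grid into inversion cells: voxels whose lateral center
#' falls inside the region-of-interest box (centered at the lesion location)
#' are individual fine cells; the remaining voxels are grouped into coarse
#' lateral blocks of `coarse_lateral_spacing` per depth layer. This is the
#' dual-mesh device that keeps the number of unknowns n of the Born inverse
#' problem small while resolving the lesion finely.
#'
#' Cell ids are ordered fine cells first (in voxel order) then coarse blocks,
#' so a mesh whose ROI covers the whole grid has `cell_assignment` equal to
#' the identity.
#'
#' @param grid an `imaging_grid`.
#' @param roi_center lesion location, numeric length 2 or 3 (x, y\[, z\]) in
#'   cm; only the lateral components define the fine box.
#' @param roi_halfwidth half-width of the fine lateral box in cm (>= 0).
#' @return A `dual_mesh` with `cell_assignment` (integer per voxel),
#'   `n_cells`, `n_fine`, per-cell voxel counts and the fine-region box.
#' @export
make_dual_mesh <- function(grid, roi_center, roi_halfwidth) {
  stopifnot(inherits(grid, "imaging_grid"))
  roi_center <- as.numeric(roi_center)
  if (length(roi_center) < 2) stop("roi_center needs x and y components")
  cx <- roi_center[1]; cy <- roi_center[2]
  half <- grid$lateral_extent / 2
  if (abs(cx) > half || abs(cy) > half) stop("roi_center outside the grid")
  if (!is.finite(roi_halfwidth) || roi_halfwidth < 0) {
    stop("roi_halfwidth must be >= 0")
  }
  box <- c(
    xmin = max(cx - roi_halfwidth, -half), xmax = min(cx + roi_halfwidth, half),
    ymin = max(cy - roi_halfwidth, -half), ymax = min(cy + roi_halfwidth, half)
  )
  vc <- voxel_centers(grid)
  in_box <- vc[, 1] >= box["xmin"] & vc[, 1] <= box["xmax"] &
    vc[, 2] >= box["ymin"] & vc[, 2] <= box["ymax"]

  assignment <- integer(nrow(vc))
  n_fine <- sum(in_box)
  assignment[in_box] <- seq_len(n_fine)

  # coarse blocks: lateral tiling anchored at the grid corner, truncated
  # blocks at the edges keep their partial size
  bs <- grid$coarse_lateral_spacing
  bx <- pmin(floor((vc[, 1] + half) / bs), ceiling(grid$lateral_extent / bs) - 1)
  by <- pmin(floor((vc[, 2] + half) / bs), ceiling(grid$lateral_extent / bs) - 1)
  layer <- rep(seq_len(grid$nz), each = grid$nx * grid$ny)
  block_key <- paste(bx, by, layer, sep = ":")[!in_box]
  if (length(block_key)) {
    block_id <- match(block_key, unique(block_key))
    assignment[!in_box] <- n_fine + block_id
  }
  n_cells <- max(assignment)
  counts <- tabulate(assignment, nbins = n_cells)
  structure(
    list(
      grid = grid,
      fine_region = box,
      cell_assignment = assignment,
      n_cells = n_cells,
      n_fine = n_fine,
      cell_voxel_counts = counts,
      cell_is_fine = seq_len(n_cells) <= n_fine
    ),
    class = "dual_mesh"
  )
}

#' @export
print.dual_mesh <- function(x, ...) {
  cat(sprintf(
    "Dual mesh: %d cells (%d fine voxels, %d coarse blocks) over %d voxels\n",
    x$n_cells, x$n_fine, x$n_cells - x$n_fine, length(x$cell_assignment)
  ))
  invisible(x)
}

#' Broadcast per-cell values to the full fine voxel grid
#'
#' Coarse-cell values are replicated uniformly over their member voxels.
#'
#' @param mesh a `dual_mesh`.
#' @param values numeric vector of length `mesh$n_cells`.
#' @return 3-D array (nx, ny, nz) on the fine grid.
#' @export
cells_to_voxels <- function(mesh, values) {
  stopifnot(length(values) == mesh$n_cells)
  array(values[mesh$cell_assignment],
        dim = c(mesh$grid$nx, mesh$grid$ny, mesh$grid$nz))
}

#' Aggregate a per-voxel field to per-cell values (sum or mean)
#' @param mesh a `dual_mesh`.
#' @param field 3-D array or vector over fine voxels.
#' @param fun "sum" or "mean" over member voxels.
#' @return numeric vector of length `mesh$n_cells`.
#' @export
voxels_to_cells <- function(mesh, field, fun = c("mean", "sum")) {
  fun <- match.arg(fun)
  v <- as.numeric(field)
  stopifnot(length(v) == length(mesh$cell_assignment))
  s <- as.numeric(rowsum(v, mesh$cell_assignment))
  if (fun == "mean") s <- s / mesh$cell_voxel_counts
  s
}
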