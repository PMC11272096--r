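#' Background optical properties of the medium
#'
#' Holds the homogeneous background absorption and reduced scattering
#' coefficients together with the derived diffusion constant
#' `D = 1/(3 (mua + musp))` (cm) and photon speed `v = c / n` (cm/s) used by
#' the frequency-domain diffusion model of a semi-infinite medium.
#'
#' @param mua background absorption coefficient, cm^-1.
#' @param musp background reduced scattering coefficient, cm^-1.
#' @param refractive_index tissue refractive index (default 1.4).
#' @param r_eff effective internal reflection coefficient of the tissue/air
#'   boundary used by the extrapolated-boundary condition (default 0.493 for
#'   n = 1.4).
#' @return An `optical_properties` object with fields `D`, `v`, `z_b`
#'   (extrapolated boundary offset `2 D (1 + R_eff) / (1 - R_eff)`).
#' @export
optical_properties <- function(mua = 0.04, musp = 6,
                               refractive_index = 1.4, r_eff = 0.493) {
  if (mua <= 0 || musp <= 0) stop("mua and musp must be > 0")
  D <- 1 / (3 * (mua + musp))
  v <- 2.99792458e10 / refractive_index
  structure(
    list(
      mua = mua, musp = musp, refractive_index = refractive_index,
      r_eff = r_eff, D = D, v = v,
      z_b = 2 * D * (1 + r_eff) / (1 - r_eff)
    ),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "Optical properties: mua %.3f cm^-1, musp %.2f cm^-1, D %.4f cm\n",
    x$mua, x$musp, x$D
  ))
  invisible(x)
}

# complex photon-density wavenumber, k^2 = (-v mua + i omega) / (v D),
# principal square root (Im k > 0 so exp(i k r) decays)
.pdw_wavenumber <- function(props, omega) {
  sqrt(complex(real = -props$v * props$mua, imaginary = omega) /
         (props$v * props$D))
}

# vectorized semi-infinite Green's function for coordinate matrices (n x 3)
.greens_semiinf <- function(ra, rb, props, omega) {
  k <- .pdw_wavenumber(props, omega)
  dx <- ra[, 1] - rb[, 1]
  dy <- ra[, 2] - rb[, 2]
  r1 <- sqrt(dx^2 + dy^2 + (ra[, 3] - rb[, 3])^2)
  # image source mirrored about the extrapolated plane z = -z_b
  r2 <- sqrt(dx^2 + dy^2 + (ra[, 3] + rb[, 3] + 2 * props$z_b)^2)
  if (any(r1 < 1e-9)) stop("coincident points: Green's function is singular")
  (exp(1i * k * r1) / r1 - exp(1i * k * r2) / r2) / (4 * pi * props$D)
}

#' Frequency-domain semi-infinite-medium Green's function
#'
#' Photon-density-wave Green's function of the diffusion equation in a
#' semi-infinite medium with an extrapolated zero boundary, implemented with a
#' single image source mirrored about the plane `z = -z_b`:
#' `G = [exp(i k r1)/r1 - exp(i k r2)/r2] / (4 pi D)` with
#' `k = sqrt((-v mua + i omega) / (v D))` (principal branch, so the wave
#' decays with distance). At `omega = 0` the value is real; on the
#' extrapolated plane it vanishes by construction.
#'
#' @param r_a,r_b points in cm; numeric length-3 vectors or (n x 3) matrices
#'   (recycled row-wise against each other).
#' @param props an [optical_properties()].
#' @param omega angular modulation frequency, rad/s.
#' @return complex vector of Green's function values (cm^-2 up to source
#'   normalization).
#' @export
greens_function <- function(r_a, r_b, props, omega) {
  ra <- if (is.matrix(r_a)) r_a else matrix(r_a, ncol = 3)
  rb <- if (is.matrix(r_b)) r_b else matrix(r_b, ncol = 3)
  n <- max(nrow(ra), nrow(rb))
  if (nrow(ra) == 1 && n > 1) ra <- ra[rep(1, n), , drop = FALSE]
  if (nrow(rb) == 1 && n > 1) rb <- rb[rep(1, n), , drop = FALSE]
  .greens_semiinf(ra, rb, props, omega)
}

# per-optode Green's function tables against all voxel centers.
# Sources and detectors are both modeled as isotropic points one transport
# length (1/musp) below their surface positions; this keeps source-detector
# exchange an exact symmetry of the weight matrix.
.optode_greens <- function(positions, vc, props, omega) {
  z0 <- 1 / props$musp
  t(vapply(seq_len(nrow(positions)), function(i) {
    p <- positions[i, ]
    .greens_semiinf(matrix(c(p[1], p[2], z0), 1), vc, props, omega)
  }, complex(nrow(vc))))
}

#' Born sensitivity (weight) matrix
#'
#' Builds the m x n complex weight matrix of the linearized (Born) DOT
#' problem `Usc = W dmua`, on the cells of a dual mesh. The per-voxel entry
#' for measurement i = (source s, detector d) and voxel j is
#' `-(v / D) * G(r_s, r_j) * G(r_j, r_d) * voxel_volume`; a coarse-cell
#' column is the sum of its member voxels' entries. Measurements are ordered
#' source-major, detector-minor.
#'
#' @param probe a [probe_geometry()].
#' @param mesh a [make_dual_mesh()] dual mesh (pass an all-fine mesh for a
#'   per-voxel matrix).
#' @param grid the `imaging_grid` the mesh was built on.
#' @param props an [optical_properties()].
#' @return A `weight_matrix` object with complex `entries` (m x n_cells),
#'   `cell_volumes` (cm^3), and the generating geometry.
#' @export
build_weight_matrix <- function(probe, mesh, grid, props) {
  stopifnot(inherits(probe, "probe_geometry"), inherits(mesh, "dual_mesh"))
  if (any(probe$source_positions[, 3] > 1e-12) ||
      any(probe$detector_positions[, 3] > 1e-12)) {
    stop("optode inside the volume (z > 0)")
  }
  omega <- 2 * pi * probe$modulation_frequency
  vc <- voxel_centers(grid)
  gs <- .optode_greens(probe$source_positions, vc, props, omega)
  gd <- .optode_greens(probe$detector_positions, vc, props, omega)
  ns <- nrow(gs); nd <- nrow(gd)
  scale <- -(props$v / props$D) * voxel_volume(grid)
  # per-voxel rows (source-major, detector-minor), then aggregate columns
  wv <- gs[rep(seq_len(ns), each = nd), , drop = FALSE] *
    gd[rep(seq_len(nd), times = ns), , drop = FALSE] * scale
  grp <- mesh$cell_assignment
  wre <- t(rowsum(t(Re(wv)), grp))
  wim <- t(rowsum(t(Im(wv)), grp))
  entries <- matrix(complex(real = wre, imaginary = wim),
                    nrow = ns * nd, ncol = mesh$n_cells)
  structure(
    list(
      entries = entries,
      cell_volumes = mesh$cell_voxel_counts * voxel_volume(grid),
      probe = probe, mesh = mesh, grid = grid, props = props,
      omega = omega
    ),
    class = "weight_matrix"
  )
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("Born weight matrix: %d measurements x %d cells\n",
              nrow(x$entries), ncol(x$entries)))
  invisible(x)
}

#' Synthesize the scattered-field perturbation (Born forward model)
#'
#' Exact matrix-vector product `Usc = W dmua`, linear in the absorption
#' perturbation.
#'
#' @param W a [build_weight_matrix()] result.
#' @param dmua per-cell absorption perturbation, cm^-1, length `n_cells`.
#' @return A `perturbation` object: complex vector of length m
#'   (source-major, detector-minor ordering).
#' @export
forward_perturbation <- function(W, dmua) {
  stopifnot(inherits(W, "weight_matrix"))
  if (length(dmua) != ncol(W$entries)) {
    stop("dmua length must equal the number of mesh cells")
  }
  v <- as.vector(W$entries %*% as.numeric(dmua))
  structure(v, class = "perturbation")
}

#' Realify a complex perturbation vector
#'
#' Stacks real parts then imaginary parts, the 2m-real representation used by
#' the conjugate-gradient solver internals and as the bottleneck regression
#' target of the network.
#'
#' @param usc complex vector (a `perturbation`).
#' @return numeric vector of length 2m.
#' @export
realify_perturbation <- function(usc) {
  c(Re(unclass(usc)), Im(unclass(usc)))
}

#' Degradation specification for measurement corruption
#'
#' Parameterizes the measurement-level degradation modes the enhancement
#' network is trained to undo: per-optode complex coupling gains (poor
#' optode-tissue contact), background heterogeneity blobs (target-like
#' clutter), and complex shot noise.
#'
#' @param source_gains,detector_gains complex per-optode gain factors
#'   (default all 1 = perfect coupling).
#' @param heterogeneity_blobs list of blobs, each
#'   `list(center = c(x, y, z), radius, dmua)`; blob `dmua` should stay
#'   within +/- 50% of the background absorption.
#' @param shot_noise_sd relative noise standard deviation (fraction of the
#'   mean measurement magnitude).
#' @param seed integer RNG seed; recorded so corruption is reproducible.
#' @return A `degradation_spec`.
#' @export
degradation_spec <- function(source_gains = NULL, detector_gains = NULL,
                             heterogeneity_blobs = list(),
                             shot_noise_sd = 0, seed = 1L) {
  structure(
    list(
      source_gains = source_gains, detector_gains = detector_gains,
      heterogeneity_blobs = heterogeneity_blobs,
      shot_noise_sd = shot_noise_sd, seed = as.integer(seed)
    ),
    class = "degradation_spec"
  )
}

#' Apply measurement degradation
#'
#' Multiplies each measurement by its source gain x detector gain, adds the
#' Born response `W b` of the heterogeneity blob field b, then adds complex
#' Gaussian noise with standard deviation `shot_noise_sd * mean(|usc|)` per
#' quadrature. Deterministic given `spec$seed`.
#'
#' @param usc clean `perturbation` vector.
#' @param spec a [degradation_spec()].
#' @param W the `weight_matrix` that generated `usc` (used to propagate the
#'   blob field; may be omitted when there are no blobs).
#' @return Degraded `perturbation` vector.
#' @export
apply_degradation <- function(usc, spec, W = NULL) {
  stopifnot(inherits(spec, "degradation_spec"))
  out <- as.vector(unclass(usc))
  m <- length(out)
  if (!is.null(spec$source_gains) || !is.null(spec$detector_gains)) {
    if (is.null(W)) stop("W is required to size the gain pattern")
    ns <- nrow(W$probe$source_positions)
    nd <- nrow(W$probe$detector_positions)
    gs <- spec$source_gains %||% rep(1 + 0i, ns)
    gd <- spec$detector_gains %||% rep(1 + 0i, nd)
    stopifnot(length(gs) == ns, length(gd) == nd)
    out <- out * (gs[rep(seq_len(ns), each = nd)] *
                    gd[rep(seq_len(nd), times = ns)])
  }
  if (length(spec$heterogeneity_blobs)) {
    if (is.null(W)) stop("W is required to propagate heterogeneity blobs")
    vc <- voxel_centers(W$grid)
    field <- numeric(nrow(vc))
    for (b in spec$heterogeneity_blobs) {
      d2 <- (vc[, 1] - b$center[1])^2 + (vc[, 2] - b$center[2])^2 +
        (vc[, 3] - b$center[3])^2
      field[d2 <= b$radius^2] <- field[d2 <= b$radius^2] + b$dmua
    }
    cell_field <- voxels_to_cells(W$mesh, field, fun = "mean")
    out <- out + as.vector(W$entries %*% cell_field)
  }
  if (spec$shot_noise_sd > 0) {
    sd_abs <- spec$shot_noise_sd * mean(Mod(out))
    out <- out + .with_seed(spec$seed, {
      complex(real = stats::rnorm(m, 0, sd_abs),
              imaginary = stats::rnorm(m, 0, sd_abs))
    })
  }
  structure(out, class = "perturbation")
}
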