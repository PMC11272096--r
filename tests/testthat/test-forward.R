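omega_default <- 2 * pi * 140.02e6

test_that("Green's function vanishes on the extrapolated plane and is real at DC", {
  p <- default_props
  g_plane <- greens_function(c(0.3, -0.2, -p$z_b), c(1, 0.5, 1.2), p,
                             omega_default)
  g_ref <- greens_function(c(1, 0.5, 0.2), c(1, 0.5, 1.2), p, omega_default)
  expect_lt(Mod(g_plane), 1e-10 * Mod(g_ref))
  # DC limit: purely real kernel
  g_dc <- greens_function(c(0, 0, 0.1), c(2, 0, 1), p, 0)
  expect_equal(Im(g_dc), 0)
  expect_error(greens_function(c(0, 0, 1), c(0, 0, 1), p, omega_default),
               "singular")
})

test_that("Green's function matches an independent evaluation of the image-source formula", {
  # scripted from scratch: wavenumber, direct + image term, all constants
  mua <- 0.04; musp <- 6; n_ref <- 1.4; r_eff <- 0.493
  D <- 1 / (3 * (mua + musp))
  v <- 2.99792458e10 / n_ref
  om <- 2 * pi * 140.02e6
  k <- sqrt((-v * mua + 1i * om) / (v * D))
  zb <- 2 * D * (1 + r_eff) / (1 - r_eff)
  ra <- c(0, 0, 0.1); rb <- c(2, 0, 1)
  r1 <- sqrt(sum((ra - rb)^2))
  r2 <- sqrt(sum((ra[1:2] - rb[1:2])^2) + (ra[3] + rb[3] + 2 * zb)^2)
  expected <- (exp(1i * k * r1) / r1 - exp(1i * k * r2) / r2) / (4 * pi * D)

  got <- greens_function(ra, rb, optical_properties(mua, musp), om)
  expect_lt(Mod(got - expected) / Mod(expected), 1e-10)
})

test_that("weight matrix has the measurement-by-cell shape and errors on bad optodes", {
  mesh <- make_dual_mesh(default_grid, c(0, 0), 1)
  W <- build_weight_matrix(default_probe, mesh, default_grid, default_props)
  expect_equal(dim(W$entries), c(126, mesh$n_cells))
  expect_true(all(is.finite(Mod(W$entries))))
  bad <- default_probe
  bad$source_positions[1, 3] <- 0.5
  expect_error(build_weight_matrix(bad, mesh, default_grid, default_props),
               "inside the volume")
})

test_that("swapping a source and detector leaves the toy-geometry entry unchanged", {
  probe_a <- probe_geometry(matrix(c(-1, 0, 0), 1), matrix(c(1, 0.5, 0), 1))
  probe_b <- probe_geometry(matrix(c(1, 0.5, 0), 1), matrix(c(-1, 0, 0), 1))
  mesh <- make_dual_mesh(toy_grid, c(0, 0), 5)
  Wa <- build_weight_matrix(probe_a, mesh, toy_grid, default_props)
  Wb <- build_weight_matrix(probe_b, mesh, toy_grid, default_props)
  expect_lt(max(Mod(Wa$entries - Wb$entries)) / max(Mod(Wa$entries)), 1e-12)
})

test_that("sensitivity decays with depth below the shallow layers", {
  mesh <- make_dual_mesh(default_grid, c(0, 0), 10) # all-fine
  W <- build_weight_matrix(default_probe, mesh, default_grid, default_props)
  norms <- matrix(sqrt(colSums(Mod(W$entries)^2)), 36 * 36, 7)
  vc <- voxel_centers(default_grid)[1:(36 * 36), 1:2]
  # strict decay from layer 2 downward everywhere under the optode array
  # (outside the probe footprint the field is diffuse and near-flat)
  under <- abs(vc[, 1]) <= 3.5 & abs(vc[, 2]) <= 3.5
  for (l in 2:6) expect_true(all(norms[under, l + 1] < norms[under, l]))
  # at optode-adjacent positions the decay holds from the surface layer
  near <- which(sqrt((vc[, 1] - 0)^2 + (vc[, 2] + 1.2)^2) < 0.3)
  expect_true(all(norms[near, 1] > norms[near, 2]))
})

test_that("Born forward model is linear and superposes targets exactly", {
  mesh <- make_dual_mesh(toy_grid, c(0, 0), 5)
  W <- build_weight_matrix(
    probe_geometry(matrix(c(-1, 0, 0, 0, -1, 0), 2, 3, byrow = TRUE),
                   matrix(c(1, 0, 0), 1)),
    mesh, toy_grid, default_props
  )
  expect_error(forward_perturbation(W, numeric(3)), "length")
  set.seed(1)
  a <- stats::runif(mesh$n_cells); b <- stats::runif(mesh$n_cells)
  expect_equal(as.vector(forward_perturbation(W, numeric(mesh$n_cells))),
               rep(0 + 0i, 2))
  f_ab <- forward_perturbation(W, a + b)
  f_sum <- unclass(forward_perturbation(W, a)) +
    unclass(forward_perturbation(W, b))
  expect_lt(max(Mod(unclass(f_ab) - f_sum)) / max(Mod(f_sum)), 1e-10)
  expect_equal(unclass(forward_perturbation(W, 2 * a)),
               2 * unclass(forward_perturbation(W, a)))
  # single-cell perturbation probes one column
  e <- numeric(mesh$n_cells); e[3] <- 0.05
  expect_equal(unclass(forward_perturbation(W, e)),
               as.vector(W$entries[, 3] * 0.05))
})

test_that("degradation modes behave as specified and are seed-deterministic", {
  mesh <- make_dual_mesh(default_grid, c(0, 0), 1)
  W <- build_weight_matrix(default_probe, mesh, default_grid, default_props)
  set.seed(7)
  usc <- structure(complex(real = rnorm(126), imaginary = rnorm(126)),
                   class = "perturbation")
  # identity spec leaves the measurement untouched
  expect_equal(unclass(apply_degradation(usc, degradation_spec(), W)),
               unclass(usc))
  # zeroing one detector gain kills its 9 measurements
  gd <- rep(1 + 0i, 14); gd[3] <- 0
  out <- apply_degradation(usc, degradation_spec(detector_gains = gd), W)
  killed <- seq(3, by = 14, length.out = 9)
  expect_true(all(Mod(unclass(out)[killed]) == 0))
  expect_equal(unclass(out)[-killed], unclass(usc)[-killed])
  # fixed seed is bitwise reproducible; includes blobs and noise
  spec <- degradation_spec(
    heterogeneity_blobs = list(list(center = c(1, 1, 1), radius = 0.8,
                                    dmua = 0.01)),
    shot_noise_sd = 0.05, seed = 123
  )
  r1 <- apply_degradation(usc, spec, W)
  r2 <- apply_degradation(usc, spec, W)
  expect_identical(r1, r2)
  expect_false(identical(unclass(r1), unclass(usc)))
})
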