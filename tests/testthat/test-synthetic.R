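test_that("target sampling honors ranges, degenerate bounds, and determinism", {
  r <- sim_parameter_ranges()
  sp <- sample_target_spec(99)
  expect_true(sp$mua_target >= 0.1 && sp$mua_target <= 0.3)
  expect_true(all(sp$size >= 1.0 - 1e-9 & sp$size <= 4.0 + 1e-9) ||
                sp$shape == "extruded_glyph")
  # degenerate range pins the draw
  r2 <- r; r2$size <- c(2, 2)
  sp2 <- sample_target_spec(5, r2)
  expect_equal(sp2$size[1], 2)
  # determinism
  expect_identical(sample_target_spec(7), sample_target_spec(7))
  # ranges outside the supported simulation envelope are rejected
  r3 <- r; r3$size <- c(1, 6)
  expect_error(sample_target_spec(1, r3), "outside")
  r4 <- r; r4$depth <- c(0.8, 5)
  expect_error(sample_target_spec(1, r4), "outside")
})

test_that("parameter coverage spans the simulation ranges", {
  specs <- lapply(1:500, sample_target_spec)
  mua <- vapply(specs, `[[`, 0, "mua_target")
  musp <- vapply(specs, `[[`, 0, "musp_target")
  d1 <- vapply(specs, function(s) s$size[1], 0)
  depth <- vapply(specs, function(s) s$center[3], 0)
  in_span <- function(x, lo, hi) {
    all(x >= lo - 1e-9 & x <= hi + 1e-9) &&
      (max(x) - min(x)) >= 0.8 * (hi - lo)
  }
  expect_true(in_span(mua, 0.1, 0.3))
  expect_true(in_span(musp, 4, 8))
  expect_true(in_span(d1, 1, 4))
  expect_true(all(depth <= 3.5))
  expect_true(all(table(vapply(specs, `[[`, "", "shape")) > 20))
})

test_that("rasterization places shapes correctly on the grid", {
  # 1 cm sphere at 1.5 cm depth spans exactly two depth layers
  sp <- target_spec("sphere", c(0, 0, 1.5), 1.0, 0.2)
  ras <- rasterize_target(sp, default_grid, 0.04)
  expect_equal(which(apply(ras$lesion_mask, 3, any)), c(3, 4))
  expect_equal(max(ras$ground_truth), 0.2 - 0.04)
  expect_true(all(ras$ground_truth[!ras$lesion_mask] == 0))
  # zero-contrast target leaves an all-zero ground truth
  sp0 <- target_spec("sphere", c(0, 0, 1.5), 1.0, 0.04)
  expect_true(all(rasterize_target(sp0, default_grid, 0.04)$ground_truth == 0))
  # voxelized sphere volume close to (4/3) pi r^3
  sp2 <- target_spec("sphere", c(0, 0, 1.75), 2.0, 0.2)
  ras2 <- rasterize_target(sp2, default_grid, 0.04)
  vol <- sum(ras2$lesion_mask) * voxel_volume(default_grid)
  expect_lt(abs(vol - 4 / 3 * pi * 1^3) / (4 / 3 * pi), 0.15)
  # target poking through the surface is rejected
  expect_error(rasterize_target(target_spec("sphere", c(0, 0, 0.3), 1, 0.2),
                                default_grid, 0.04), "surface")
})

test_that("non-spherical shapes rasterize with sensible extents", {
  cube <- rasterize_target(target_spec("cube", c(0, 0, 1.5), 1.0, 0.2),
                           default_grid, 0.04)
  expect_equal(sum(cube$lesion_mask), 4 * 4 * 2) # 1 cm cube at 0.25/0.5 res
  glyph <- rasterize_target(
    target_spec("extruded_glyph", c(0, 0, 1.5), c(2, 2, 1), 0.2,
                glyph = "star"),
    default_grid, 0.04
  )
  expect_gt(sum(glyph$lesion_mask), 10)
  # star occupies a minority of its bounding box footprint
  expect_lt(sum(glyph$lesion_mask), 0.6 * 8 * 8 * 2)
  two <- rasterize_target(
    target_spec("two_hemisphere_ball", c(0, 0, 1.5), 1.5, 0.2),
    default_grid, 0.04
  )
  # asymmetric: more voxels above the equator than below
  layers <- apply(two$lesion_mask, 3, sum)
  expect_gt(sum(layers[1:3]), sum(layers[4:7]))
})

test_that("generated samples are deterministic and physically coherent", {
  props <- optical_properties(0.04, 6)
  sp <- target_spec("sphere", c(0.5, -0.3, 2.0), 1.5, 0.15)
  s1 <- generate_sample(sp, default_probe, default_grid, props, seed = 9)
  s2 <- generate_sample(sp, default_probe, default_grid, props, seed = 9)
  expect_identical(s1, s2)
  # clean perturbation equals the Born forward of the meshed ground truth
  mesh <- make_dual_mesh(default_grid, s1$metadata$roi_center,
                         s1$metadata$roi_halfwidth)
  W <- build_weight_matrix(default_probe, mesh, default_grid, props)
  expect_equal(unclass(s1$perturbation),
               unclass(forward_perturbation(
                 W, voxels_to_cells(mesh, s1$ground_truth, "mean"))))
  # lesion lies inside the fine-mesh region
  expect_true(all(s1$fine_mesh_mask[s1$lesion_mask]))
  # zero-contrast target reconstructs to (near) nothing
  sp0 <- target_spec("sphere", c(0.5, -0.3, 2.0), 1.5, 0.04 + 1e-9)
  s0 <- generate_sample(sp0, default_probe, default_grid, props, seed = 9)
  expect_lt(max(s0$input_recon), 1e-6)
})

test_that("deep noiseless target reconstructs with a usable amplitude", {
  props <- optical_properties(0.04, 6)
  sp <- target_spec("sphere", c(0, 0, 2.5), 1.5, 0.12)
  s <- generate_sample(sp, default_probe, default_grid, props, seed = 4,
                       source_hotspots = FALSE)
  ratio <- max(s$input_recon) / max(s$ground_truth)
  # linear dual-mesh inversion strongly under-reconstructs deep targets
  # (the phenomenon the enhancement network corrects); the recovered
  # maximum is positive and bounded by the true contrast
  expect_gt(ratio, 0.02)
  expect_lt(ratio, 1.1)
  # a shallower target recovers a larger fraction of the true contrast
  sp_shallow <- target_spec("sphere", c(0, 0, 1.2), 1.5, 0.12)
  s2 <- generate_sample(sp_shallow, default_probe, default_grid, props,
                        seed = 4, source_hotspots = FALSE)
  expect_gt(max(s2$input_recon) / max(s2$ground_truth), ratio)
})

test_that("shallow targets receive source hot-spot contamination", {
  props <- optical_properties(0.04, 6)
  sp <- target_spec("sphere", c(0, 0, 1.0), 1.4, 0.2)
  clean <- generate_sample(sp, default_probe, default_grid, props, seed = 2,
                           source_hotspots = FALSE)
  hot <- generate_sample(sp, default_probe, default_grid, props, seed = 2,
                         source_hotspots = TRUE)
  expect_true(hot$metadata$hotspots)
  expect_gt(sum(hot$input_recon[, , 1]), sum(clean$input_recon[, , 1]))
  # deep target: no hot spots injected
  spd <- target_spec("sphere", c(0, 0, 2.5), 1.4, 0.2)
  deep <- generate_sample(spd, default_probe, default_grid, props, seed = 2)
  expect_false(deep$metadata$hotspots)
})

test_that("dataset generation honors counts, splits, and artifact fractions", {
  ds <- generate_dataset(10, splits = c(train = 0.8, val = 0.1, test = 0.1),
                         config = list(seed = 5))
  expect_length(ds$samples, 10)
  expect_equal(ds$manifest$n_samples, 10)
  expect_equal(sum(unlist(ds$manifest$splits)), 10)
  expect_setequal(unique(ds$split), c("train", "val", "test"))
  # all-single-target configuration
  ds1 <- generate_dataset(6, config = list(seed = 6, fraction_multi = 0))
  expect_true(all(vapply(ds1$samples,
                         function(s) s$metadata$n_targets, 0L) == 1L))
  # artifact fraction within a binomial window (n = 60, p = 0.4)
  ds2 <- generate_dataset(60, config = list(seed = 7, fraction_artifact = 0.4,
                                            source_hotspots = FALSE))
  k <- sum(vapply(ds2$samples, function(s) s$metadata$artifact, TRUE))
  expect_gt(k, 60 * 0.4 - 3 * sqrt(60 * 0.4 * 0.6))
  expect_lt(k, 60 * 0.4 + 3 * sqrt(60 * 0.4 * 0.6))
  expect_error(generate_dataset(0), ">= 1")
})
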