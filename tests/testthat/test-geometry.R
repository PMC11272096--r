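test_that("default probe has the clinical optode layout", {
  p <- default_probe
  expect_s3_class(p, "probe_geometry")
  expect_equal(nrow(p$source_positions), 9)
  expect_equal(nrow(p$detector_positions), 14)
  expect_equal(n_measurements(p), 126)
  expect_equal(p$modulation_frequency, 140.02e6)
  # probe plane convention
  expect_true(all(p$source_positions[, 3] == 0))
  expect_true(all(p$detector_positions[, 3] == 0))
  # all optodes inside the 9 cm aperture
  all_pos <- rbind(p$source_positions, p$detector_positions)
  expect_true(all(abs(all_pos[, 1:2]) <= 4.5))
  # minimum source-detector separation well clear of the overlap regime
  sd_dist <- sqrt(outer(p$source_positions[, 1], p$detector_positions[, 1],
                        "-")^2 +
                  outer(p$source_positions[, 2], p$detector_positions[, 2],
                        "-")^2)
  expect_gt(min(sd_dist), 0.5)
})

test_that("probe constructor rejects degenerate layouts", {
  expect_error(probe_geometry(matrix(c(0, 0, 1), 1), matrix(c(0, 0, 0), 1)),
               "z = 0")
  expect_error(probe_geometry(matrix(c(0, 0, 0), 1), matrix(c(0, 0, 0), 1)),
               "coincide")
  expect_error(probe_geometry(matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1),
                              modulation_frequency = 0), "> 0")
})

test_that("default grid matches the seven-layer reconstruction volume", {
  g <- default_grid
  expect_equal(g$nz, 7)
  expect_equal(c(g$nx, g$ny), c(36, 36))
  expect_equal(g$nx * g$ny * g$nz, 9072)
  expect_equal(voxel_volume(g), 0.25^2 * 0.5)
  vc <- voxel_centers(g)
  # voxel centers strictly inside the volume, at cell midpoints
  expect_true(all(abs(vc[, 1:2]) < 4.5))
  expect_true(all(vc[, 3] > 0 & vc[, 3] < 3.5))
  expect_equal(sort(unique(vc[, 3])), 0.5 * (1:7) - 0.25)
})

test_that("grid handles custom extents and rejects bad spacings", {
  g <- build_grid(lateral_extent = 3, coarse_lateral_spacing = 1.5)
  expect_equal(ceiling(g$lateral_extent / g$coarse_lateral_spacing), 2)
  expect_error(build_grid(fine_lateral_spacing = -1), "positive")
  expect_error(build_grid(lateral_extent = 9, fine_lateral_spacing = 0.26),
               "divide")
})

test_that("dual mesh degenerate partitions have the expected cell counts", {
  all_fine <- make_dual_mesh(default_grid, c(0, 0), 10)
  expect_equal(all_fine$n_cells, 9072)
  expect_equal(all_fine$cell_assignment, seq_len(9072))

  all_coarse <- make_dual_mesh(default_grid, c(0, 0), 0)
  expect_equal(all_coarse$n_cells, 6 * 6 * 7)
  expect_equal(all_coarse$n_fine, 0)
})

test_that("dual mesh cell count matches a brute-force voxel labeling", {
  mesh <- make_dual_mesh(default_grid, c(0, 0), 1)
  # independent labeling: walk every voxel, build cell keys from scratch
  vc <- voxel_centers(default_grid)
  keys <- character(nrow(vc))
  for (v in seq_len(nrow(vc))) {
    x <- vc[v, 1]; y <- vc[v, 2]; z <- vc[v, 3]
    if (abs(x) <= 1 && abs(y) <= 1) {
      keys[v] <- sprintf("fine:%f:%f:%f", x, y, z)
    } else {
      keys[v] <- sprintf("coarse:%d:%d:%f",
                         floor((x + 4.5) / 1.5), floor((y + 4.5) / 1.5), z)
    }
  }
  expect_equal(mesh$n_cells, length(unique(keys)))
  expect_equal(mesh$n_fine, sum(startsWith(keys, "fine")))
  expect_lt(mesh$n_cells, 9072)
})

test_that("dual mesh is a partition and refines monotonically", {
  set.seed(3)
  prev_cells <- 0
  for (hw in c(0.4, 0.9, 1.7, 2.6)) {
    mesh <- make_dual_mesh(default_grid, c(0.6, -0.4), hw)
    # partition: every voxel in exactly one cell, counts add up
    expect_equal(sum(mesh$cell_voxel_counts), 9072)
    expect_true(all(mesh$cell_assignment >= 1 &
                      mesh$cell_assignment <= mesh$n_cells))
    expect_true(all(tabulate(mesh$cell_assignment, mesh$n_cells) ==
                      mesh$cell_voxel_counts))
    # enlarging the ROI never decreases the number of cells
    expect_gte(mesh$n_cells, prev_cells)
    prev_cells <- mesh$n_cells
  }
  expect_error(make_dual_mesh(default_grid, c(7, 0), 1), "outside")
})

test_that("cell/voxel broadcast and aggregation are mutually consistent", {
  mesh <- make_dual_mesh(default_grid, c(0, 0), 1.2)
  vals <- stats::runif(mesh$n_cells)
  vol <- cells_to_voxels(mesh, vals)
  expect_equal(dim(vol), c(36, 36, 7))
  expect_equal(voxels_to_cells(mesh, vol, "mean"), vals)
  expect_equal(voxels_to_cells(mesh, vol, "sum"),
               vals * mesh$cell_voxel_counts)
})
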