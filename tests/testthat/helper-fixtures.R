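# shared small fixtures (built once per test run)

default_probe <- build_default_probe()
default_grid <- build_grid()
default_props <- optical_properties(0.04, 6)

# a 3 x 3 x 1.5 cm toy grid (12 x 12 x 3 voxels) for cheap physics tests
toy_grid <- build_grid(lateral_extent = 3, depth_extent = 1.5,
                       fine_lateral_spacing = 0.25,
                       coarse_lateral_spacing = 1.5,
                       layer_thickness = 0.5)

# synthetic meshless weight matrix wrapper for solver oracle tests
raw_weight_matrix <- function(entries) {
  structure(list(entries = entries, mesh = NULL), class = "weight_matrix")
}

# plain-config solver settings matching the identity-penalty normal equations
plain_recon <- function(lambda, tol = 1e-12, iters = 1000) {
  recon_config(lambda = lambda, residual_tolerance = tol,
               max_iterations = iters, nonnegativity = FALSE,
               depth_compensation = 0)
}

random_complex_matrix <- function(m, n) {
  matrix(complex(real = stats::rnorm(m * n), imaginary = stats::rnorm(m * n)),
         m, n)
}

# tiny network configuration used by the model unit tests
tiny_net_config <- function(...) {
  args <- utils::modifyList(
    list(grid_size = 12, n_layers = 2, spatial = 8, n_blocks = 2,
         base_channels = 3, fc_width = 10, perturbation_dim = 6),
    list(...)
  )
  do.call(apunet_config, args)
}

tiny_input <- function(n = 2, seed = 5) {
  set.seed(seed)
  list(recon = array(abs(rnorm(12 * 12 * 2 * n, 0, 0.05)), c(12, 12, 2, n)),
       mask = array(rbinom(12 * 12 * 2 * n, 1, 0.3), c(12, 12, 2, n)) * 1.0)
}
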