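# Small, fast simulation settings shared across tests.

quick_props <- function() optical_properties(mu_a = 0.5, mu_s = 5, g = 0.9)

quick_grid <- function(n = 40L, h = 0.05) voxel_grid(rep(n, 3L), h)

quick_mc <- function(n_photons = 2e4, seed = 1, props = quick_props(),
                     grid = quick_grid(), source = source_spec()) {
  run_mc(source, grid, props, n_photons = n_photons, seed = seed)
}

# hand-built fluence map (already in normalized units)
manual_fluence <- function(values, grid) {
  structure(list(values = values, grid = grid,
                 source = source_spec(), props = quick_props(),
                 n_photons = 1, seed = 0, source_fluence_per_exit = 1,
                 totals = list()),
            class = "fluence_map")
}

# polygon area by the shoelace formula (oracle for contour tests)
shoelace <- function(x, y) {
  n <- length(x)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# fast small synthetic trial set
quick_protocol <- function(shape = c(48L, 48L), n_stim = 6L, n_blank = 6L,
                           n_frames = 40L) {
  acquisition_protocol(n_frames = n_frames, n_trials_stim = n_stim,
                       n_trials_blank = n_blank, image_shape = shape)
}

quick_truth <- function(...) {
  args <- list(center = c(24.5, 24.5), spatial_sigma = 6,
               peak_amplitude = -2.2e-4, noise_sigma = 0)
  args[names(list(...))] <- list(...)
  do.call(ground_truth_activation, args)
}
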