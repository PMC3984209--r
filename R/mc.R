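#' Run a voxel Monte-Carlo photon transport simulation
#'
#' Traces `n_photons` from the source through a homogeneous scattering
#' medium using hop-drop-spin transport with absorption weighting: each
#' interaction deposits `w * mu_a / mu_t` of the photon weight into the
#' enclosing voxel, the remainder is scattered through a Henyey-Greenstein
#' polar angle and uniform azimuth, and photons below `rr_threshold` are
#' terminated unbiasedly by Russian roulette. Photons leaving the grid are
#' counted as escaped (the source sits deep in tissue; no internal
#' reflection at the domain boundary).
#'
#' The absorbed-energy estimate per voxel is converted to fluence by
#' dividing by `mu_a * voxel volume * n_photons`, and the map is then
#' normalized so that the intensity value at the source is one: the map
#' maximum, which sits at the source exit, is scaled to 1, and `values`
#' are dimensionless multiples of it. Multiplying by the measured
#' intensity at the fiber tip gives physical fluence in mW/mm^2 (see
#' [threshold_volume()]). The alternative normalization by the source
#' exit intensity I0 = P / (pi r^2) is reachable through the recorded
#' conversion factor `source_fluence_per_exit` (the source fluence in I0
#' units, > 1 in scattering tissue because of backscatter).
#'
#' @param source a [source_spec()] (or [fiber_config()] via [make_source()])
#' @param grid a [voxel_grid()]
#' @param props an [optical_properties()]; `mu_a` must be positive for the
#'   absorbed-energy fluence estimator
#' @param n_photons photons to launch (default 1e7)
#' @param seed integer seed for the simulation's own xoshiro256** RNG;
#'   required, echoed into the result
#' @param rr_threshold Russian-roulette weight threshold (default 1e-4)
#' @param rr_survival roulette survival probability (default 0.1)
#' @param max_steps safety cap on interactions per photon
#' @return an object of class `fluence_map`: list with `values` (3-D array
#'   of normalized fluence), `grid`, `n_photons`, `seed`,
#'   `source_fluence_per_exit`, and a `totals` list recording the weight
#'   ledger (deposited, escaped, roulette loss/gain, and the largest
#'   per-photon balance error)
#' @examples
#' \donttest{
#' fm <- run_mc(source_spec(), voxel_grid(c(50, 50, 50), 0.04),
#'              brain_optics_473(), n_photons = 1e4, seed = 1)
#' max(fm$values)
#' }
#' @export
run_mc <- function(source, grid, props, n_photons = 1e7, seed,
                   rr_threshold = 1e-4, rr_survival = 0.1,
                   max_steps = 1e6) {
  if (inherits(source, "fiber_config")) source <- make_source(source)
  stopifnot(inherits(source, "source_spec"), inherits(grid, "voxel_grid"),
            inherits(props, "optical_properties"))
  if (missing(seed)) stop("'seed' is required for reproducibility")
  if (props$mu_a <= 0)
    stop("mu_a = 0 is unsupported: the absorbed-energy fluence estimator ",
         "divides by mu_a; use a small positive mu_a instead")
  n_photons <- as.numeric(n_photons)
  if (n_photons < 1) stop("'n_photons' must be >= 1")

  res <- cpp_run_mc(grid$shape, grid$voxel_size, grid$origin,
                    props$mu_a, props$mu_s, props$g,
                    source$center, source$normal, source$radius,
                    source$half_angle, source$angular == "isotropic",
                    n_photons, as.numeric(seed) %% 2^63,
                    rr_threshold, rr_survival, max_steps)

  vol <- grid$voxel_size^3
  scale <- pi * source$radius^2 / (props$mu_a * vol * n_photons)
  values <- array(res$deposit * scale, dim = grid$shape)
  # the fluence maximum sits at the source exit; normalizing to it makes
  # "intensity at the source" equal one
  phi0 <- max(values)
  if (!is.finite(phi0) || phi0 <= 0) {
    warning("empty fluence map; leaving it in exit-intensity units")
    phi0 <- 1
  }
  structure(list(values = values / phi0, grid = grid, source = source,
                 props = props, n_photons = n_photons, seed = seed,
                 source_fluence_per_exit = phi0,
                 totals = list(deposited = res$deposited,
                               escaped = res$escaped,
                               rr_loss = res$rr_loss,
                               rr_gain = res$rr_gain,
                               max_balance_err = res$max_balance_err)),
            class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("Fluence map (%d x %d x %d voxels of %g mm)\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$grid$voxel_size))
  cat(sprintf("  %s photons, seed %s; peak fluence %.3g x I0\n",
              format(x$n_photons, big.mark = ","), format(x$seed),
              max(x$values)))
  with(x$totals, cat(sprintf(
    "  weight ledger: deposited %.4f, escaped %.4f (of 1 per photon)\n",
    deposited / x$n_photons, escaped / x$n_photons)))
  invisible(x)
}

#' Propagate a single photon
#'
#' Traces one photon with a given initial state through the medium and
#' returns its full weight ledger together with the deposition array. This
#' exposes the transport kernel one photon at a time, mainly for testing
#' conservation and limiting cases (`mu_s = 0` Beer-Lambert deposition,
#' `mu_a = 0` pure escape).
#'
#' @param position length-3 start position (mm); must lie inside the grid
#' @param direction length-3 direction (normalized internally)
#' @param grid a [voxel_grid()]
#' @param props an [optical_properties()]; `mu_a = 0` is allowed here
#' @param seed RNG seed
#' @param weight launch weight (default 1)
#' @param rr_threshold,rr_survival Russian-roulette parameters; set
#'   `rr_threshold = 0` to disable roulette
#' @param max_steps cap on interactions
#' @return list with `deposit` (3-D array of deposited weight), `deposited`,
#'   `escaped`, `rr_loss`, `rr_gain` and `balance_err` (absolute deviation
#'   of the ledger from the launched weight)
#' @export
propagate_photon <- function(position, direction, grid, props, seed,
                             weight = 1, rr_threshold = 1e-4,
                             rr_survival = 0.1, max_steps = 1e6) {
  stopifnot(inherits(grid, "voxel_grid"),
            inherits(props, "optical_properties"),
            is.numeric(position), length(position) == 3L,
            is.numeric(direction), length(direction) == 3L,
            weight >= 0, weight <= 1)
  rel <- (position - grid$origin) / grid$voxel_size
  if (any(rel < 0) || any(rel >= grid$shape))
    stop("photon start position lies outside the grid")
  dn <- sqrt(sum(direction^2))
  if (dn == 0) stop("'direction' must be a nonzero vector")
  res <- cpp_propagate(as.numeric(position), as.numeric(direction) / dn,
                       weight, grid$shape, grid$voxel_size, grid$origin,
                       props$mu_a, props$mu_s, props$g,
                       as.numeric(seed) %% 2^63, rr_threshold, rr_survival,
                       max_steps)
  res$deposit <- array(res$deposit, dim = grid$shape)
  res
}

#' Voxel center coordinates of a grid axis
#'
#' @param grid a [voxel_grid()]
#' @param axis 1, 2 or 3
#' @return numeric vector of voxel-center coordinates (mm)
#' @export
voxel_centers <- function(grid, axis) {
  stopifnot(inherits(grid, "voxel_grid"), axis %in% 1:3)
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$voxel_size
}

#' Write / read a fluence map as NIfTI + JSON sidecar
#'
#' The voxel values go into a NIfTI-1 volume (a standard format for
#' 3-D grids that volume viewers open directly) with the voxel size
#' recorded in its header; the simulation metadata (optical properties,
#' source, photon count, seed, weight ledger) goes into a JSON sidecar at
#' `<path>.json`. `read_fluence()` restores the full `fluence_map`.
#'
#' @param fm a `fluence_map` from [run_mc()]
#' @param path output path (conventionally ending in `.nii` or `.nii.gz`)
#' @return `write_fluence()` returns `path` invisibly; `read_fluence()`
#'   returns a `fluence_map`
#' @export
write_fluence <- function(fm, path) {
  stopifnot(inherits(fm, "fluence_map"))
  img <- RNifti::asNifti(fm$values)
  RNifti::pixdim(img) <- rep(fm$grid$voxel_size, 3)
  RNifti::writeNifti(img, path)
  meta <- list(grid = fm$grid[c("shape", "voxel_size", "origin")],
               source = unclass(fm$source), props = unclass(fm$props),
               n_photons = fm$n_photons, seed = fm$seed,
               source_fluence_per_exit = fm$source_fluence_per_exit,
               totals = fm$totals)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fluence
#' @export
read_fluence <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- array(as.numeric(RNifti::readNifti(path)),
                  dim = as.integer(meta$grid$shape))
  grid <- voxel_grid(meta$grid$shape, meta$grid$voxel_size, meta$grid$origin)
  source <- source_spec(meta$source$center, meta$source$normal,
                        meta$source$radius, meta$source$half_angle,
                        meta$source$angular)
  props <- optical_properties(meta$props$mu_a, meta$props$mu_s, meta$props$g,
                              meta$props$n)
  structure(list(values = values, grid = grid, source = source, props = props,
                 n_photons = meta$n_photons, seed = meta$seed,
                 source_fluence_per_exit = meta$source_fluence_per_exit,
                 totals = meta$totals),
            class = "fluence_map")
}
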