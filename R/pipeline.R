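# End-to-end drivers chaining the Monte-Carlo engine to the activation-
# volume analysis, with a reproducibility manifest. Sweeps derive an
# independent seed per configuration from the base seed so configurations
# are statistically independent but jointly reproducible.

.derive_seed <- function(seed, i) {
  (as.numeric(seed) + i * 1000003) %% 2^31
}

#' Activated volume as a function of source intensity
#'
#' Runs one Monte-Carlo simulation for the given fiber pose and thresholds
#' the fluence map at the ChR2 threshold for each source exit intensity,
#' yielding the activated-volume vs. intensity table (the light-intensity
#' titration of the stimulated tissue volume).
#'
#' @param config a [fiber_config()]
#' @param intensities source exit intensities I0 (mW/mm^2)
#' @param threshold activation fluence threshold (mW/mm^2)
#' @param grid,props simulation domain and tissue optics
#' @param n_photons,seed Monte-Carlo settings (see [run_mc()])
#' @param fluence optionally, a precomputed `fluence_map` (then the MC
#'   settings are ignored)
#' @param out_dir if non-NULL, write `volumes.csv` and a run manifest there
#' @return data.frame with columns `intensity`, `threshold`, `n_voxels`,
#'   `volume_mm3`; the fluence map is attached as attribute `"fluence"`
#' @export
activation_volume_series <- function(config = fiber_config(),
                                     intensities = c(1.4, 2.2, 3.2),
                                     threshold = 0.5,
                                     grid = voxel_grid(),
                                     props = brain_optics_473(),
                                     n_photons = 1e7, seed = 1,
                                     fluence = NULL, out_dir = NULL) {
  if (is.null(fluence))
    fluence <- run_mc(make_source(config, props$n), grid, props,
                      n_photons = n_photons, seed = seed)
  rows <- lapply(intensities, function(i0) {
    m <- threshold_volume(fluence, i0, threshold)
    data.frame(intensity = i0, threshold = threshold,
               n_voxels = sum(m$mask), volume_mm3 = m$volume)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(out, file.path(out_dir, "volumes.csv"), row.names = FALSE)
    write_run_manifest(out_dir, list(config = unclass(config),
                                     intensities = intensities,
                                     threshold = threshold,
                                     n_photons = fluence$n_photons),
                       seed, "volumes.csv")
  }
  attr(out, "fluence") <- fluence
  out
}

#' Activated-volume overlap across a fiber sweep
#'
#' Runs one Monte-Carlo simulation per fiber pose in a rotation and/or
#' translation sweep, thresholds each fluence map at the same intensity
#' and threshold, and reports the pairwise overlap of consecutive poses in
#' all three overlap conventions. For a pure rotation sweep the pose list
#' is treated as cyclic (the last angle is adjacent to the first) when
#' `cyclic = TRUE`.
#'
#' Each pose gets an independent seed derived from `seed`, so the compared
#' masks carry independent Monte-Carlo noise, and the sweep as a whole is
#' reproducible.
#'
#' @param base a [fiber_config()]
#' @param phis rotation angles (degrees)
#' @param depth_offsets axial offsets (mm)
#' @param intensity source exit intensity I0 (mW/mm^2)
#' @param threshold activation fluence threshold (mW/mm^2)
#' @param grid,props simulation domain and tissue optics
#' @param n_photons,seed Monte-Carlo settings
#' @param cyclic close the sweep into a ring (default: only when more than
#'   2 poses)
#' @param out_dir if non-NULL, write `overlaps.csv` and a manifest there
#' @return data.frame with one row per consecutive pair: labels, single
#'   volumes, and `overlap_mean`, `overlap_jaccard`, `overlap_min`
#' @export
overlap_sweep <- function(base = fiber_config(), phis = 0,
                          depth_offsets = 0, intensity = 2.2,
                          threshold = 0.5, grid = voxel_grid(),
                          props = brain_optics_473(), n_photons = 1e7,
                          seed = 1, cyclic = NULL, out_dir = NULL) {
  configs <- sweep_configs(base, phis, depth_offsets)
  if (length(configs) < 2) stop("a sweep needs at least 2 poses")
  if (is.null(cyclic)) cyclic <- length(configs) > 2
  masks <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    fl <- run_mc(make_source(configs[[i]], props$n), grid, props,
                 n_photons = n_photons, seed = .derive_seed(seed, i))
    masks[[i]] <- threshold_volume(fl, intensity, threshold)
  }
  pairs <- cbind(seq_along(configs),
                 c(seq_along(configs)[-1], 1L))
  if (!cyclic) pairs <- pairs[-nrow(pairs), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    data.frame(label_a = configs[[i]]$label, label_b = configs[[j]]$label,
               volume_a = masks[[i]]$volume, volume_b = masks[[j]]$volume,
               overlap_mean = overlap_fraction(masks[[i]], masks[[j]], "mean"),
               overlap_jaccard = overlap_fraction(masks[[i]], masks[[j]],
                                                  "jaccard"),
               overlap_min = overlap_fraction(masks[[i]], masks[[j]], "min"))
  }))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(out, file.path(out_dir, "overlaps.csv"), row.names = FALSE)
    write_run_manifest(out_dir, list(base = unclass(base), phis = phis,
                                     depth_offsets = depth_offsets,
                                     intensity = intensity,
                                     threshold = threshold,
                                     n_photons = n_photons),
                       seed, "overlaps.csv")
  }
  out
}

#' Write a reproducibility manifest
#'
#' Records the configuration, base seed, package version and MD5 checksums
#' of the listed output files as `manifest.json` in `dir`, so a run can be
#' reproduced and its outputs verified bit for bit.
#'
#' @param dir output directory
#' @param config list of configuration values (serialized as JSON)
#' @param seed base seed of the run
#' @param files character vector of file names relative to `dir`
#' @return the manifest path, invisibly
#' @export
write_run_manifest <- function(dir, config, seed, files) {
  sums <- tools::md5sum(file.path(dir, files))
  manifest <- list(
    package = "sidefire",
    version = as.character(utils::packageVersion("sidefire")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    outputs = data.frame(file = files, md5 = unname(sums)))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
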