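#' Threshold a fluence map at the ChR2 activation irradiance
#'
#' Converts a normalized fluence map (intensity at the source normalized
#' to one, see [run_mc()]) into the set of voxels where the physical
#' fluence rate exceeds the channelrhodopsin-2 activation threshold: a
#' voxel is active iff `fluence * source_intensity > threshold`.
#' ChR2-expressing neurons fire at half-maximum rate near 0.5 mW/mm^2 of
#' 473 nm light, the default threshold; 0.49 mW/mm^2 is an equally
#' supported convention. With `normalization = "exit"` the map is instead
#' scaled so that `source_intensity` is read as the exit intensity
#' I0 = P / (pi r^2) rather than as the fluence at the source.
#'
#' @param fluence a `fluence_map` from [run_mc()]
#' @param source_intensity light intensity at the fiber tip (mW/mm^2)
#' @param threshold activation fluence threshold (mW/mm^2); default 0.5
#' @param normalization `"source"` (default): `source_intensity` is the
#'   fluence at the source, matching the map normalization; `"exit"`:
#'   `source_intensity` is the exit intensity I0
#' @return an object of class `activation_mask`: list with logical `mask`
#'   array, `volume` (mm^3), `grid`, `source_intensity`, `threshold`
#' @export
threshold_volume <- function(fluence, source_intensity, threshold = 0.5,
                             normalization = c("source", "exit")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(fluence, "fluence_map"),
            is.numeric(source_intensity), length(source_intensity) == 1L,
            is.numeric(threshold), length(threshold) == 1L)
  if (source_intensity <= 0) stop("'source_intensity' must be > 0")
  if (threshold <= 0) stop("'threshold' must be > 0")
  v <- fluence$values
  if (normalization == "exit")
    v <- v * fluence$source_fluence_per_exit
  mask <- v > threshold / source_intensity
  vol <- sum(mask) * fluence$grid$voxel_size^3
  if (vol == 0)
    warning("threshold exceeds the maximum attained fluence: empty mask")
  structure(list(mask = mask, volume = vol, grid = fluence$grid,
                 source_intensity = source_intensity, threshold = threshold),
            class = "activation_mask")
}

#' @export
print.activation_mask <- function(x, ...) {
  cat(sprintf(
    "Activation mask: %d voxels, %.4g mm^3 (I0 = %g mW/mm^2, threshold %g mW/mm^2)\n",
    sum(x$mask), x$volume, x$source_intensity, x$threshold))
  invisible(x)
}

#' Spatial overlap between two activated volumes
#'
#' Fraction of overlap between the voxel sets of two activation masks on
#' the same grid. Three conventions are supported, since "percent overlap"
#' is ambiguous for unequal volumes:
#' \describe{
#'   \item{mean}{intersection over the mean single-mask volume,
#'     `|A & B| / ((|A| + |B|) / 2)` (default; for masks congruent under a
#'     pure rotation this coincides with `min`)}
#'   \item{jaccard}{intersection over union}
#'   \item{min}{intersection over the smaller volume}
#' }
#'
#' @param a,b `activation_mask` objects on an identical grid
#' @param mode `"mean"` (default), `"jaccard"` or `"min"`
#' @return overlap fraction in `[0, 1]`
#' @export
overlap_fraction <- function(a, b, mode = c("mean", "jaccard", "min")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "activation_mask"), inherits(b, "activation_mask"))
  if (!identical(a$grid$shape, b$grid$shape) ||
      a$grid$voxel_size != b$grid$voxel_size ||
      !isTRUE(all.equal(a$grid$origin, b$grid$origin)))
    stop("masks must share an identical grid")
  na <- sum(a$mask); nb <- sum(b$mask)
  if (na == 0 && nb == 0)
    stop("overlap is undefined for two empty masks")
  ni <- sum(a$mask & b$mask)
  switch(mode,
         mean = ni / ((na + nb) / 2),
         jaccard = ni / (na + nb - ni),
         min = ni / min(na, nb))
}

#' Isocontours of an activation mask on a planar slice
#'
#' Extracts the closed 2-D boundary contours of the mask on the slice
#' perpendicular to `axis` nearest the physical coordinate `coord`,
#' in mm in the two remaining grid axes (in ascending axis order).
#'
#' @param mask an `activation_mask`
#' @param axis slicing axis (1, 2 or 3)
#' @param coord physical coordinate (mm) of the slice along `axis`
#' @return list of contours, each a list with `x` and `y` (mm); empty list
#'   for an empty slice
#' @export
isocontour_slices <- function(mask, axis, coord) {
  stopifnot(inherits(mask, "activation_mask"), axis %in% 1:3)
  centers <- voxel_centers(mask$grid, axis)
  if (coord < mask$grid$origin[axis] ||
      coord > mask$grid$origin[axis] +
        mask$grid$shape[axis] * mask$grid$voxel_size)
    stop("'coord' does not intersect the grid")
  k <- which.min(abs(centers - coord))
  sl <- switch(axis,
               mask$mask[k, , ],
               mask$mask[, k, ],
               mask$mask[, , k])
  if (!any(sl)) return(list())
  other <- setdiff(1:3, axis)
  cx <- voxel_centers(mask$grid, other[1])
  cy <- voxel_centers(mask$grid, other[2])
  # pad with zeros so boundary-touching masks still close
  h <- mask$grid$voxel_size
  z <- matrix(0, nrow(sl) + 2, ncol(sl) + 2)
  z[2:(nrow(sl) + 1), 2:(ncol(sl) + 1)] <- sl
  cl <- contourLines(x = c(cx[1] - h, cx, cx[length(cx)] + h),
                     y = c(cy[1] - h, cy, cy[length(cy)] + h),
                     z = z, levels = 0.5)
  lapply(cl, function(ct) list(x = ct$x, y = ct$y))
}
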