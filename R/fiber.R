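#' Side-firing fiber pose
#'
#' Describes the physical pose of the implanted fiber in a right-handed
#' stereotaxic frame (x lateral, y anterior, z dorsal). The default
#' insertion axis is tilted 57 degrees from vertical in the x-z plane,
#' matching an oblique insertion through a craniotomy toward the LGN:
#' `(sin 57, 0, -cos 57)`.
#'
#' A side-firing tip (the default mode) has its mirror-coated 45-degree
#' bevel redirect the beam perpendicular to the fiber axis; `phi` selects
#' the emission direction by rotation about the axis. `phi = 0` maps to the
#' reference perpendicular obtained by projecting the global +x (lateral)
#' direction off the axis; positive `phi` rotates it by the right-hand rule
#' about the insertion axis. `mode = "axial"` models a plain flat-cleaved
#' fiber emitting along its axis. The absolute registration of `phi` to
#' anatomy varies between implantations, so it is a free parameter.
#'
#' @param tip fiber tip position (mm, length 3)
#' @param axis unit insertion-axis vector (normalized internally)
#' @param phi rotation angle about the axis (degrees, `[0, 360)`)
#' @param depth_offset signed translation along the axis (mm); positive
#'   moves the emission center further along `axis`
#' @param core_diameter fiber core diameter (mm); default 0.2
#' @param na numerical aperture (in air); default 0.37
#' @param mode `"side_firing"` or `"axial"`
#' @param surface_offset radial distance from the fiber axis to the
#'   emission disc (mm). A side-firing tip emits through the side surface
#'   of the fiber, so the disc sits about one core radius off the
#'   rotation axis; default `core_diameter / 2` in side-firing mode and 0
#'   in axial mode. This offset is what makes rotation sweeps displace
#'   the illuminated volume.
#' @param label optional label carried into sweep manifests
#' @return an object of class `fiber_config`
#' @export
fiber_config <- function(tip = c(0, 0, 0),
                         axis = c(sin(57 * pi / 180), 0, -cos(57 * pi / 180)),
                         phi = 0, depth_offset = 0, core_diameter = 0.2,
                         na = 0.37, mode = c("side_firing", "axial"),
                         surface_offset = NULL, label = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(tip), length(tip) == 3L,
            is.numeric(axis), length(axis) == 3L,
            is.numeric(phi), length(phi) == 1L,
            is.numeric(depth_offset), length(depth_offset) == 1L,
            core_diameter > 0, na > 0)
  if (is.null(surface_offset))
    surface_offset <- if (mode == "side_firing") core_diameter / 2 else 0
  stopifnot(is.numeric(surface_offset), length(surface_offset) == 1L,
            surface_offset >= 0)
  an <- sqrt(sum(axis^2))
  if (an == 0) stop("'axis' must be a nonzero vector")
  phi <- phi %% 360
  structure(list(tip = as.numeric(tip), axis = as.numeric(axis) / an,
                 phi = phi, depth_offset = depth_offset,
                 core_diameter = core_diameter, na = na, mode = mode,
                 surface_offset = surface_offset, label = label),
            class = "fiber_config")
}

#' @export
print.fiber_config <- function(x, ...) {
  cat(sprintf(
    "Fiber (%s): tip (%g, %g, %g) mm, phi = %g deg, offset = %g mm\n",
    x$mode, x$tip[1], x$tip[2], x$tip[3], x$phi, x$depth_offset))
  cat(sprintf("  core %g mm, NA %g, axis (%.3f, %.3f, %.3f)\n",
              x$core_diameter, x$na, x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

#' Rotate vectors about an axis
#'
#' Rodrigues rotation of `v` by `angle_deg` degrees about the unit vector
#' `axis` (right-hand rule).
#'
#' @param v length-3 vector
#' @param axis rotation axis (normalized internally)
#' @param angle_deg rotation angle (degrees)
#' @return rotated length-3 vector
#' @export
rotate_about_axis <- function(v, axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  v * cos(th) + c(a[2] * v[3] - a[3] * v[2],
                  a[3] * v[1] - a[1] * v[3],
                  a[1] * v[2] - a[2] * v[1]) * sin(th) +
    a * sum(a * v) * (1 - cos(th))
}

#' Build the emission disc for a fiber pose
#'
#' Converts a [fiber_config()] into the [source_spec()] consumed by
#' [run_mc()]. In side-firing mode the emission disc (radius
#' `core_diameter / 2`) has its normal perpendicular to the axis, oriented
#' by `phi`, and is centered at
#' `tip + depth_offset * axis + surface_offset * normal` — i.e. on the
#' side surface of the fiber, where the mirrored bevel emits. In axial
#' mode the normal is the axis itself and the disc is centered on it. The
#' cone half-angle in tissue is `asin(na / n_tissue)`.
#'
#' @param config a [fiber_config()]
#' @param n_tissue tissue refractive index; default 1.37
#' @return a [source_spec()]
#' @export
make_source <- function(config, n_tissue = 1.37) {
  stopifnot(inherits(config, "fiber_config"))
  if (config$na >= n_tissue)
    stop("numerical aperture must be smaller than the tissue index")
  center <- config$tip + config$depth_offset * config$axis
  if (config$mode == "axial") {
    normal <- config$axis
  } else {
    normal <- rotate_about_axis(.phi_reference(config$axis), config$axis,
                                config$phi)
    center <- center + config$surface_offset * normal
  }
  source_spec(center = center, normal = normal,
              radius = config$core_diameter / 2,
              half_angle = fiber_half_angle(config$na, n_tissue))
}

# phi = 0 reference: the lateral (+x) direction projected off the axis;
# falls back to +y when the axis is (anti)parallel to x.
.phi_reference <- function(axis) {
  r0 <- c(1, 0, 0) - axis * axis[1]
  if (sum(r0^2) < 1e-12) r0 <- c(0, 1, 0) - axis * axis[2]
  r0 / sqrt(sum(r0^2))
}

#' Enumerate fiber poses over rotations and translations
#'
#' Cartesian product of rotation angles and axial offsets applied to a base
#' pose, in row-major order (offsets vary fastest within each rotation).
#' Each configuration is labelled `phi<angle>_z<offset>`.
#'
#' @param base a [fiber_config()]
#' @param phis rotation angles (degrees), non-empty
#' @param depth_offsets axial offsets (mm), non-empty; default 0
#' @return list of [fiber_config()] objects with `label` set
#' @examples
#' sw <- sweep_configs(fiber_config(), phis = seq(0, 315, by = 45))
#' length(sw) # 8
#' @export
sweep_configs <- function(base, phis, depth_offsets = 0) {
  stopifnot(inherits(base, "fiber_config"),
            length(phis) >= 1, length(depth_offsets) >= 1)
  out <- list()
  for (phi in phis) {
    for (dz in depth_offsets) {
      cfg <- base
      cfg$phi <- phi %% 360
      cfg$depth_offset <- base$depth_offset + dz
      cfg$label <- sprintf("phi%g_z%g", phi, dz)
      out[[cfg$label]] <- cfg
    }
  }
  out
}
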