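#' Optical properties of a homogeneous tissue
#'
#' Bundles the absorption coefficient, scattering coefficient, scattering
#' anisotropy and refractive index of one tissue at one wavelength.
#' [brain_optics_473()] supplies the mouse-brain values used throughout
#' the package.
#'
#' The scattering coefficient is interpreted as the (unreduced) coefficient
#' `mu_s` to be used together with the anisotropy `g`. If a source quotes a
#' reduced coefficient mu_s' instead, pass `reduced = TRUE`: the pair is then
#' converted to the equivalent `mu_s = mu_s'/(1 - g)`.
#'
#' @param mu_a absorption coefficient (mm^-1), >= 0
#' @param mu_s scattering coefficient (mm^-1), >= 0
#' @param g scattering anisotropy (mean cosine of the deflection angle),
#'   in (-1, 1)
#' @param n refractive index, >= 1
#' @param reduced if `TRUE`, `mu_s` is taken as the reduced scattering
#'   coefficient mu_s' and converted to `mu_s'/(1 - g)`
#' @return an object of class `optical_properties`
#' @examples
#' optical_properties(mu_a = 0.05, mu_s = 2, g = 0)
#' brain_optics_473()
#' @export
optical_properties <- function(mu_a, mu_s, g = 0, n = 1.37,
                               reduced = FALSE) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L, is.finite(mu_a),
            is.numeric(mu_s), length(mu_s) == 1L, is.finite(mu_s),
            is.numeric(g), length(g) == 1L, is.finite(g),
            is.numeric(n), length(n) == 1L, is.finite(n))
  if (mu_a < 0) stop("'mu_a' must be >= 0")
  if (mu_s < 0) stop("'mu_s' must be >= 0")
  if (abs(g) >= 1) stop("'g' must lie strictly between -1 and 1")
  if (n < 1) stop("'n' must be >= 1")
  if (reduced) mu_s <- mu_s / (1 - g)
  if (mu_a + mu_s <= 0) stop("total attenuation mu_a + mu_s must be > 0")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "optical_properties")
}

#' Mouse-brain optical properties at 473 nm
#'
#' The tissue model used for all default simulations: absorption
#' 0.48 mm^-1, reduced scattering 4.37 mm^-1 with anisotropy g = 0.9
#' (equivalently mu_s = 43.7 mm^-1), refractive index 1.37. The 4.37 mm^-1
#' brain-scattering value circulating in the tissue-optics literature at
#' this wavelength is a reduced coefficient: combined with g = 0.9 it gives
#' a transport mean free path of ~0.2 mm, in line with measured brain
#' turbidity, whereas reading it as an unreduced mu_s would imply
#' mu_s' = 0.44 mm^-1 and a nearly transparent brain. Pass
#' `reduced = FALSE` to adopt that alternative reading anyway.
#'
#' @param reduced interpret 4.37 mm^-1 as the reduced coefficient
#'   (default `TRUE`)
#' @return an [optical_properties()] object
#' @export
brain_optics_473 <- function(reduced = TRUE) {
  optical_properties(mu_a = 0.48, mu_s = 4.37, g = 0.9, n = 1.37,
                     reduced = reduced)
}

#' @export
print.optical_properties <- function(x, ...) {
  cat("Optical properties:\n")
  cat(sprintf("  mu_a = %g mm^-1, mu_s = %g mm^-1, g = %g, n = %g\n",
              x$mu_a, x$mu_s, x$g, x$n))
  cat(sprintf("  mu_t = %g mm^-1, mu_s' = %g mm^-1\n",
              x$mu_a + x$mu_s, x$mu_s * (1 - x$g)))
  invisible(x)
}

#' Define a voxel grid
#'
#' A regular isotropic voxel grid over which fluence is accumulated. The
#' default covers a 2 x 2 x 2 mm cube of 10 um voxels centered on the
#' origin, which comfortably contains every above-threshold voxel at the
#' source intensities studied while resolving a 200 um emission disc.
#'
#' @param shape integer triple, number of voxels per axis
#' @param voxel_size voxel edge length (mm)
#' @param origin position of the grid corner (mm); defaults to centering the
#'   grid on (0, 0, 0)
#' @return an object of class `voxel_grid`
#' @export
voxel_grid <- function(shape = c(200L, 200L, 200L), voxel_size = 0.01,
                       origin = -shape * voxel_size / 2) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            is.numeric(voxel_size), length(voxel_size) == 1L, voxel_size > 0,
            is.numeric(origin), length(origin) == 3L, all(is.finite(origin)))
  structure(list(shape = shape, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  ext <- x$shape * x$voxel_size
  cat(sprintf("Voxel grid: %d x %d x %d voxels of %g mm (%g x %g x %g mm)\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size,
              ext[1], ext[2], ext[3]))
  invisible(x)
}

#' Photon emission disc
#'
#' Describes the light source as a flat disc emitting into a cone: photons
#' start uniformly over the disc and travel within `half_angle` of the disc
#' normal, uniformly in solid angle (a top-hat far field, the usual model
#' for a multimode fiber). `angular = "isotropic"` emits uniformly over the
#' full sphere instead and is used to validate the transport kernel against
#' diffusion theory.
#'
#' @param center disc center (mm, length 3)
#' @param normal emission direction (length 3, normalized internally)
#' @param radius disc radius (mm), > 0
#' @param half_angle emission cone half-angle in tissue (radians), in
#'   `[0, pi/2)`
#' @param angular `"cone"` (default) or `"isotropic"`
#' @return an object of class `source_spec`
#' @seealso [fiber_half_angle()] to derive `half_angle` from a numerical
#'   aperture, [make_source()] to build the source from a fiber pose
#' @export
source_spec <- function(center = c(0, 0, 0), normal = c(0, 0, 1),
                        radius = 0.1, half_angle = fiber_half_angle(),
                        angular = c("cone", "isotropic")) {
  angular <- match.arg(angular)
  stopifnot(is.numeric(center), length(center) == 3L, all(is.finite(center)),
            is.numeric(normal), length(normal) == 3L, all(is.finite(normal)),
            is.numeric(radius), length(radius) == 1L,
            is.numeric(half_angle), length(half_angle) == 1L)
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("'normal' must be a nonzero vector")
  if (radius <= 0) stop("'radius' must be > 0")
  if (half_angle < 0 || half_angle >= pi / 2)
    stop("'half_angle' must lie in [0, pi/2)")
  structure(list(center = as.numeric(center), normal = as.numeric(normal) / nn,
                 radius = radius, half_angle = half_angle, angular = angular),
            class = "source_spec")
}

#' @export
print.source_spec <- function(x, ...) {
  cat(sprintf(
    "Emission disc: radius %g mm at (%g, %g, %g), %s\n", x$radius,
    x$center[1], x$center[2], x$center[3],
    if (x$angular == "isotropic") "isotropic" else
      sprintf("cone half-angle %.4f rad (%.2f deg) about (%.3f, %.3f, %.3f)",
              x$half_angle, x$half_angle * 180 / pi,
              x$normal[1], x$normal[2], x$normal[3])))
  invisible(x)
}

#' In-tissue emission half-angle of a fiber
#'
#' The numerical aperture of a fiber is quoted in air (NA = sin of the
#' half-angle of the emission cone in air). Refraction at the tissue
#' interface conserves NA, so the divergence half-angle inside tissue of
#' refractive index `n_tissue` is `asin(NA / n_tissue)`.
#'
#' @param na numerical aperture (in air); default 0.37 (200 um multimode
#'   fiber)
#' @param n_tissue tissue refractive index; default 1.37 (brain)
#' @return half-angle in radians
#' @examples
#' fiber_half_angle(0.37, 1.37) # ~0.2737 rad, 15.68 deg
#' @export
fiber_half_angle <- function(na = 0.37, n_tissue = 1.37) {
  stopifnot(is.numeric(na), length(na) == 1L,
            is.numeric(n_tissue), length(n_tissue) == 1L)
  if (na <= 0 || na >= n_tissue)
    stop("'na' must lie in (0, n_tissue)")
  asin(na / n_tissue)
}

#' Sample a photon free path length
#'
#' Inverse-CDF sample of the exponential free-path distribution with total
#' attenuation `mu_t`: `-log(u) / mu_t`. The expectation over uniform `u`
#' is the mean free path `1 / mu_t`.
#'
#' @param u uniform variates in (0, 1]
#' @param mu_t total attenuation coefficient (mm^-1), > 0
#' @return path lengths (mm), vectorized over `u`
#' @export
sample_free_path <- function(u, mu_t) {
  stopifnot(is.numeric(u), is.numeric(mu_t), length(mu_t) == 1L)
  if (!is.finite(mu_t) || mu_t <= 0) stop("'mu_t' must be > 0")
  if (any(!is.finite(u)) || any(u <= 0) || any(u > 1))
    stop("'u' must lie in (0, 1]")
  -log(u) / mu_t
}

#' Sample a Henyey-Greenstein scattering cosine
#'
#' Inverse-CDF sample of the Henyey-Greenstein phase function with
#' anisotropy `g`: for `g != 0`,
#' `cos(theta) = (1 + g^2 - ((1 - g^2) / (1 - g + 2 g u))^2) / (2 g)`;
#' for `g = 0` the scattering is isotropic and `cos(theta) = 2 u - 1`.
#' The first moment of the sampled cosine equals `g`.
#'
#' @param u uniform variates in `[0, 1)`
#' @param g anisotropy factor, in (-1, 1)
#' @return scattering cosines in `[-1, 1]`, vectorized over `u`
#' @export
sample_hg_cosine <- function(u, g) {
  stopifnot(is.numeric(u), is.numeric(g), length(g) == 1L)
  if (!is.finite(g) || abs(g) >= 1) stop("'g' must lie in (-1, 1)")
  if (any(!is.finite(u)) || any(u < 0) || any(u >= 1))
    stop("'u' must lie in [0, 1)")
  if (g == 0) return(2 * u - 1)
  f <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - f^2) / (2 * g)))
}

#' Launch photons from an emission disc
#'
#' Draws initial photon states for a [source_spec()]: positions uniform over
#' the disc, directions uniform in solid angle within the emission cone
#' (or over the sphere for an isotropic source), weight 1. Uses R's RNG;
#' call `set.seed()` for reproducibility. This is the R-level reference for
#' the launch step; [run_mc()] performs the same sampling in compiled code.
#'
#' @param source a [source_spec()]
#' @param n number of photons
#' @return list with `position` (n x 3), `direction` (n x 3, unit rows) and
#'   `weight` (all 1)
#' @export
launch_photon <- function(source, n = 1L) {
  stopifnot(inherits(source, "source_spec"), n >= 1)
  n <- as.integer(n)
  b <- .disc_basis(source$normal)
  r <- source$radius * sqrt(runif(n))
  th <- 2 * pi * runif(n)
  pos <- matrix(source$center, n, 3, byrow = TRUE) +
    outer(r * cos(th), b$e1) + outer(r * sin(th), b$e2)
  if (source$angular == "isotropic") {
    ca <- 2 * runif(n) - 1
  } else {
    ca <- 1 - runif(n) * (1 - cos(source$half_angle))
  }
  sa <- sqrt(pmax(0, 1 - ca^2))
  ph <- 2 * pi * runif(n)
  dir <- outer(sa * cos(ph), b$e1) + outer(sa * sin(ph), b$e2) +
    outer(ca, source$normal)
  list(position = pos, direction = dir, weight = rep(1, n))
}

# orthonormal basis perpendicular to a unit vector (matches the C++ kernel)
.disc_basis <- function(n) {
  e1 <- if (abs(n[1]) < 0.9) c(0, -n[3], n[2]) else c(-n[3], 0, n[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2)
}
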