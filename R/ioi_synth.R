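#' Intrinsic-optical-imaging acquisition protocol
#'
#' Trial structure of the imaging experiment the generator emulates: 20 s
#' trials of 80 camera frames at 4 Hz, a pre-stimulus period of 8 frames
#' (2 s), a 250 ms optogenetic stimulus starting at frame 9, and 20
#' stimulus plus 20 blank trials in randomized order.
#'
#' @param n_frames frames per trial (default 80)
#' @param frame_rate acquisition rate (Hz, default 4)
#' @param n_prestim pre-stimulus frames (default 8)
#' @param stim_duration stimulus duration (s, default 0.25)
#' @param n_trials_stim,n_trials_blank trial counts (default 20 each)
#' @param image_shape rows x cols of each frame (default 128 x 128)
#' @param pixel_size image scale (mm/pixel, default 0.01)
#' @return an object of class `acquisition_protocol`
#' @export
acquisition_protocol <- function(n_frames = 80L, frame_rate = 4,
                                 n_prestim = 8L, stim_duration = 0.25,
                                 n_trials_stim = 20L, n_trials_blank = 20L,
                                 image_shape = c(128L, 128L),
                                 pixel_size = 0.01) {
  stopifnot(n_frames >= 1, n_prestim >= 1, n_prestim < n_frames,
            frame_rate > 0, stim_duration > 0,
            n_trials_stim >= 1, n_trials_blank >= 1,
            length(image_shape) == 2L, all(image_shape >= 1),
            pixel_size > 0)
  structure(list(n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 n_prestim = as.integer(n_prestim),
                 stim_duration = stim_duration,
                 n_trials_stim = as.integer(n_trials_stim),
                 n_trials_blank = as.integer(n_trials_blank),
                 image_shape = as.integer(image_shape),
                 pixel_size = pixel_size),
            class = "acquisition_protocol")
}

#' Ground-truth activation for the synthetic generator
#'
#' The generator's hidden truth: a spatially Gaussian reflectance response
#' (an inverted, deoxygenation-driven dip of order -0.01% to -0.03% of
#' baseline) whose time course is a gamma-variate hemodynamic response
#' peaking a few seconds after stimulus onset, on top of i.i.d.
#' multiplicative Gaussian pixel noise.
#'
#' @param center response center in pixel coordinates (row, col); default
#'   the image center of a 128 x 128 frame
#' @param spatial_sigma Gaussian spatial SD (pixels)
#' @param peak_amplitude peak fractional reflectance change at the center;
#'   negative for a reflectance decrease (default -2.2e-4, i.e. -0.022%)
#' @param hrf_peak_time time of the response peak after stimulus onset (s)
#' @param hrf_width full width at half maximum of the response (s)
#' @param baseline baseline reflectance level (arbitrary camera units)
#' @param noise_sigma fractional noise SD per pixel per frame
#' @return an object of class `ground_truth_activation`
#' @export
ground_truth_activation <- function(center = c(64.5, 64.5),
                                    spatial_sigma = 12,
                                    peak_amplitude = -2.2e-4,
                                    hrf_peak_time = 2.5, hrf_width = 3,
                                    baseline = 1000, noise_sigma = 1e-4) {
  stopifnot(length(center) == 2L, spatial_sigma > 0, hrf_peak_time > 0,
            hrf_width > 0, baseline > 0, noise_sigma >= 0,
            is.numeric(peak_amplitude), length(peak_amplitude) == 1L)
  structure(list(center = as.numeric(center), spatial_sigma = spatial_sigma,
                 peak_amplitude = peak_amplitude,
                 hrf_peak_time = hrf_peak_time, hrf_width = hrf_width,
                 baseline = baseline, noise_sigma = noise_sigma),
            class = "ground_truth_activation")
}

# shape parameter of the gamma-variate (t/tp)^a exp(a (1 - t/tp)) whose
# FWHM equals `width` for peak time `tp`
.hrf_shape <- function(tp, width) {
  fwhm <- function(a) {
    lf <- function(tau) a * log(tau) + a * (1 - tau) + log(2)
    t1 <- uniroot(lf, c(1e-9, 1), tol = 1e-12)$root
    t2 <- uniroot(lf, c(1, 1e3), tol = 1e-12)$root
    tp * (t2 - t1)
  }
  uniroot(function(a) fwhm(a) - width, c(0.05, 200), tol = 1e-10)$root
}

#' Hemodynamic response multiplier per frame
#'
#' The per-frame reflectance multiplier at the response center: exactly 1
#' during the pre-stimulus frames, then `1 + peak_amplitude * k(t)` where
#' `k` is a gamma-variate kernel `(t/tp)^a exp(a (1 - t/tp))` normalized to
#' 1 at `hrf_peak_time` with shape `a` chosen to give the requested FWHM.
#' Stimulus onset is at the first post-pre-stimulus frame.
#'
#' @param protocol an [acquisition_protocol()]
#' @param truth a [ground_truth_activation()]
#' @return numeric vector of length `n_frames`
#' @export
hrf_timecourse <- function(protocol, truth) {
  stopifnot(inherits(protocol, "acquisition_protocol"),
            inherits(truth, "ground_truth_activation"))
  t_frame <- (seq_len(protocol$n_frames) - 1) / protocol$frame_rate
  onset <- protocol$n_prestim / protocol$frame_rate
  tpost <- t_frame - onset
  k <- numeric(protocol$n_frames)
  if (truth$peak_amplitude != 0) {
    a <- .hrf_shape(truth$hrf_peak_time, truth$hrf_width)
    pos <- tpost > 0
    tau <- tpost[pos] / truth$hrf_peak_time
    k[pos] <- tau^a * exp(a * (1 - tau))
  }
  1 + truth$peak_amplitude * k
}

#' Generate a synthetic IOI trial set
#'
#' Stimulus trials are `baseline * (1 + (m_f - 1) * G(x, y))` where `m_f`
#' is the [hrf_timecourse()] multiplier and `G` the unit-peak spatial
#' Gaussian of the ground truth, multiplied by `(1 + e)` with
#' `e ~ N(0, noise_sigma)` i.i.d. per pixel and frame. Blank trials carry
#' the baseline and noise only. Stimulus and blank conditions are
#' interleaved in an order randomized by `seed`; the whole set is
#' deterministic given `seed` and R's global RNG state is left untouched.
#'
#' @param protocol an [acquisition_protocol()]
#' @param truth a [ground_truth_activation()]
#' @param seed integer seed
#' @return an object of class `ioi_trials`: list with `data` (trial x
#'   frame x row x col array), `condition` (factor `"stim"`/`"blank"` per
#'   trial), `protocol`, `truth`, `seed`
#' @export
generate_trials <- function(protocol, truth, seed) {
  stopifnot(inherits(protocol, "acquisition_protocol"),
            inherits(truth, "ground_truth_activation"))
  if (missing(seed)) stop("'seed' is required for reproducibility")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  nr <- protocol$image_shape[1]
  nc <- protocol$image_shape[2]
  ntr <- protocol$n_trials_stim + protocol$n_trials_blank
  condition <- sample(rep(c("stim", "blank"),
                          c(protocol$n_trials_stim, protocol$n_trials_blank)))
  m <- hrf_timecourse(protocol, truth)
  g <- outer(seq_len(nr) - truth$center[1], seq_len(nc) - truth$center[2],
             function(dr, dc) exp(-(dr^2 + dc^2) /
                                    (2 * truth$spatial_sigma^2)))

  data <- array(0, dim = c(ntr, protocol$n_frames, nr, nc))
  flat <- nr * nc
  for (tr in seq_len(ntr)) {
    stim <- condition[tr] == "stim"
    for (f in seq_len(protocol$n_frames)) {
      clean <- if (stim) truth$baseline * (1 + (m[f] - 1) * g) else
        matrix(truth$baseline, nr, nc)
      noise <- if (truth$noise_sigma > 0) {
        1 + rnorm(flat, sd = truth$noise_sigma)
      } else 1
      data[tr, f, , ] <- clean * noise
    }
  }
  structure(list(data = data, condition = factor(condition,
                                                 c("stim", "blank")),
                 protocol = protocol, truth = truth, seed = seed),
            class = "ioi_trials")
}

#' @export
print.ioi_trials <- function(x, ...) {
  cat(sprintf(
    "IOI trial set: %d stim + %d blank trials, %d frames of %d x %d px (seed %s)\n",
    sum(x$condition == "stim"), sum(x$condition == "blank"),
    x$protocol$n_frames, x$protocol$image_shape[1], x$protocol$image_shape[2],
    format(x$seed)))
  invisible(x)
}

#' Half-maximum footprint of the ground-truth response
#'
#' Closed form for the set of pixels whose expected peak response exceeds
#' half the center amplitude: a disc of radius
#' `spatial_sigma * sqrt(2 log 2)` pixels, hence area
#' `2 pi log(2) * spatial_sigma^2` pixels (times `pixel_size^2` in mm^2).
#' Used as the ground truth in area-recovery tests.
#'
#' @param truth a [ground_truth_activation()]
#' @param pixel_size mm per pixel (default 0.01)
#' @return list with `radius_px`, `area_px`, `area_mm2`
#' @export
half_max_footprint <- function(truth, pixel_size = 0.01) {
  stopifnot(inherits(truth, "ground_truth_activation"))
  r <- truth$spatial_sigma * sqrt(2 * log(2))
  area_px <- pi * r^2
  list(radius_px = r, area_px = area_px,
       area_mm2 = area_px * pixel_size^2)
}

#' Write / read an IOI trial set as TIFF stacks + JSON sidecar
#'
#' Each trial becomes one multi-page 16-bit TIFF (`trial_001.tif`, ...)
#' under `dir`, linearly rescaled to the global data range; the affine
#' scale, protocol, condition labels, truth parameters and seed go into
#' `stack.json`. The round trip is lossless up to the 16-bit quantization
#' step recorded in the sidecar.
#'
#' @param trials an `ioi_trials` set from [generate_trials()]
#' @param dir output directory (created if needed)
#' @return `write_stack()` returns `dir` invisibly; `read_stack()` returns
#'   an `ioi_trials` object
#' @export
write_stack <- function(trials, dir) {
  stopifnot(inherits(trials, "ioi_trials"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  lo <- min(trials$data)
  hi <- max(trials$data)
  if (hi <= lo) hi <- lo + 1
  ntr <- dim(trials$data)[1]
  for (tr in seq_len(ntr)) {
    pages <- lapply(seq_len(dim(trials$data)[2]), function(f) {
      (trials$data[tr, f, , ] - lo) / (hi - lo)
    })
    tiff::writeTIFF(pages, file.path(dir, sprintf("trial_%03d.tif", tr)),
                    bits.per.sample = 16L)
  }
  meta <- list(format_version = 1L,
               protocol = unclass(trials$protocol),
               truth = unclass(trials$truth),
               condition = as.character(trials$condition),
               seed = trials$seed,
               scale = list(lo = lo, hi = hi,
                            step = (hi - lo) / 65535))
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  p <- meta$protocol
  protocol <- acquisition_protocol(p$n_frames, p$frame_rate, p$n_prestim,
                                   p$stim_duration, p$n_trials_stim,
                                   p$n_trials_blank, p$image_shape,
                                   p$pixel_size)
  tr <- meta$truth
  truth <- ground_truth_activation(tr$center, tr$spatial_sigma,
                                   tr$peak_amplitude, tr$hrf_peak_time,
                                   tr$hrf_width, tr$baseline, tr$noise_sigma)
  ntr <- length(meta$condition)
  data <- array(0, dim = c(ntr, protocol$n_frames, protocol$image_shape))
  for (i in seq_len(ntr)) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("trial_%03d.tif", i)),
                            all = TRUE)
    for (f in seq_along(pages)) {
      data[i, f, , ] <- pages[[f]] * (meta$scale$hi - meta$scale$lo) +
        meta$scale$lo
    }
  }
  structure(list(data = data,
                 condition = factor(meta$condition, c("stim", "blank")),
                 protocol = protocol, truth = truth, seed = meta$seed),
            class = "ioi_trials")
}
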