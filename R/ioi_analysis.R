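#' Average trials of one condition and normalize to the pre-stimulus level
#'
#' Averages all trials of the requested condition frame by frame, then
#' divides each pixel's time course by its own mean over the pre-stimulus
#' frames, so the pre-stimulus level is 1 everywhere and responses appear
#' as fractional deviations from 1.
#'
#' @param trials an `ioi_trials` set from [generate_trials()] or
#'   [read_stack()]
#' @param condition `"stim"` or `"blank"`
#' @return an object of class `normalized_stack`: list with `values`
#'   (frame x row x col), `protocol`, `condition`, `n_trials`
#' @export
average_and_normalize <- function(trials, condition = c("stim", "blank")) {
  condition <- match.arg(condition)
  stopifnot(inherits(trials, "ioi_trials"))
  sel <- which(trials$condition == condition)
  if (length(sel) < 1) stop("no trials of condition '", condition, "'")
  d <- dim(trials$data)
  avg <- array(0, dim = d[2:4])
  for (tr in sel) avg <- avg + trials$data[tr, , , ]
  avg <- avg / length(sel)

  pre <- seq_len(trials$protocol$n_prestim)
  nr <- d[3]; nc <- d[4]
  pre_mean <- matrix(colMeans(matrix(avg[pre, , ], length(pre), nr * nc)),
                     nr, nc)
  if (any(pre_mean == 0))
    stop("degenerate input: zero pre-stimulus mean at some pixel")
  values <- avg / rep(pre_mean, each = d[2])
  structure(list(values = values, protocol = trials$protocol,
                 condition = condition, n_trials = length(sel)),
            class = "normalized_stack")
}

#' @export
print.normalized_stack <- function(x, ...) {
  cat(sprintf(
    "Normalized stack: %d frames of %d x %d px (%s, mean of %d trials)\n",
    dim(x$values)[1], dim(x$values)[2], dim(x$values)[3], x$condition,
    x$n_trials))
  invisible(x)
}

# 1-D Gaussian smoothing matrix with truncated, renormalized rows
.gauss_matrix <- function(n, sigma) {
  half <- ceiling(4 * sigma)
  i <- seq_len(n)
  s <- matrix(0, n, n)
  for (d in -half:half) {
    j <- i + d
    ok <- j >= 1 & j <= n
    s[cbind(i[ok], j[ok])] <- dnorm(d, sd = sigma)
  }
  s / rowSums(s)
}

#' Gaussian spatial filter of a normalized stack
#'
#' Convolves each frame with an isotropic Gaussian of standard deviation
#' `sigma` pixels (separable kernel truncated at 4 sigma; boundary weights
#' are renormalized, so constant frames pass unchanged). `sigma = 0` is
#' the identity. The default 4 px matches common IOI practice of smoothing
#' activation maps before delimiting areas.
#'
#' @param stack a `normalized_stack` (or bare frame x row x col array)
#' @param sigma Gaussian SD in pixels, >= 0
#' @return object of the same class with filtered `values`
#' @export
spatial_filter <- function(stack, sigma = 4) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("'sigma' must be a single number >= 0")
  v <- if (inherits(stack, "normalized_stack")) stack$values else stack
  if (sigma > 0) {
    d <- dim(v)
    sr <- .gauss_matrix(d[2], sigma)
    sc <- t(.gauss_matrix(d[3], sigma))
    for (f in seq_len(d[1])) v[f, , ] <- sr %*% v[f, , ] %*% sc
  }
  if (inherits(stack, "normalized_stack")) {
    stack$values <- v
    stack
  } else v
}

#' Pixelwise t-statistic activation map
#'
#' For every pixel, a two-sided Welch (unequal-variance) two-sample t-test
#' comparing the pre-stimulus frames of the trial-averaged stack against
#' the frames of the response window. Pixels with `p < alpha` form the
#' significant mask; no multiple-testing correction is applied by default,
#' matching common per-pixel practice in IOI (`correct = "BH"` switches to
#' Benjamini-Hochberg adjusted p-values).
#'
#' The stimulus itself occupies a single frame at 4 Hz, so the response
#' window defaults to the 16 frames after onset (0-4 s, covering the
#' hemodynamic peak); it must be disjoint from the pre-stimulus frames and
#' both windows need at least 2 frames.
#'
#' @param stack a `normalized_stack` (typically after [spatial_filter()])
#' @param response_window integer vector of frame indices; default
#'   `n_prestim + 1` through `n_prestim + 16`
#' @param alpha significance level (default 0.05)
#' @param correct `"none"` (default) or `"BH"`
#' @return an object of class `activation_map`: `t_map`, `p_map`, `mask`,
#'   `alpha`, `area` (mm^2), `pixel_size`
#' @export
t_map <- function(stack, response_window = NULL, alpha = 0.05,
                  correct = c("none", "BH")) {
  correct <- match.arg(correct)
  stopifnot(inherits(stack, "normalized_stack"), alpha > 0, alpha < 1)
  pre <- seq_len(stack$protocol$n_prestim)
  if (is.null(response_window))
    response_window <- stack$protocol$n_prestim +
      seq_len(min(16L, dim(stack$values)[1] - stack$protocol$n_prestim))
  response_window <- as.integer(response_window)
  if (length(intersect(pre, response_window)) > 0)
    stop("response window must be disjoint from the pre-stimulus frames")
  if (length(pre) < 2 || length(response_window) < 2)
    stop("both windows need at least 2 frames")
  d <- dim(stack$values)
  npx <- d[2] * d[3]
  x1 <- matrix(stack$values[pre, , ], length(pre), npx)
  x2 <- matrix(stack$values[response_window, , ], length(response_window),
               npx)
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums((x1 - rep(m1, each = n1))^2) / (n1 - 1)
  v2 <- colSums((x2 - rep(m2, each = n2))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  pp <- 2 * pt(-abs(tt), df)
  if (correct == "BH") pp <- stats::p.adjust(pp, method = "BH")
  t_arr <- matrix(tt, d[2], d[3])
  p_arr <- matrix(pp, d[2], d[3])
  mask <- p_arr < alpha
  ps <- stack$protocol$pixel_size
  structure(list(t_map = t_arr, p_map = p_arr, mask = mask, alpha = alpha,
                 area = sum(mask) * ps^2, pixel_size = ps,
                 response_window = response_window),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf(
    "Activation map: %d significant pixels (%.4g mm^2) at alpha = %g\n",
    sum(x$mask), x$area, x$alpha))
  invisible(x)
}

#' Area of the significant-pixel mask
#'
#' The activated cortical area: number of pixels where the null hypothesis
#' was rejected, times the pixel area.
#'
#' @param map an `activation_map`
#' @param pixel_size mm per pixel; defaults to the value carried by `map`
#' @return area in mm^2
#' @export
activation_area <- function(map, pixel_size = map$pixel_size) {
  stopifnot(inherits(map, "activation_map"))
  sum(map$mask) * pixel_size^2
}

#' Centroid of the significant mask
#'
#' @param map an `activation_map`
#' @return `(row, col)` centroid in pixel coordinates, or `c(NA, NA)` for
#'   an empty mask
#' @export
mask_centroid <- function(map) {
  stopifnot(inherits(map, "activation_map"))
  idx <- which(map$mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(NA_real_, NA_real_))
  colMeans(idx)
}

#' Peak response amplitude over a region
#'
#' Averages the normalized time course over the pixels of `mask` and
#' returns the signed extremum deviation from baseline over the
#' post-stimulus frames, in percent (negative for a reflectance decrease).
#'
#' @param stack a `normalized_stack`
#' @param mask logical row x col matrix (e.g. from an `activation_map`)
#' @return peak fractional change in percent
#' @export
peak_amplitude <- function(stack, mask) {
  stopifnot(inherits(stack, "normalized_stack"), is.logical(mask))
  if (!any(mask)) stop("peak amplitude is undefined for an empty mask")
  d <- dim(stack$values)
  v <- matrix(stack$values, d[1], d[2] * d[3])
  tc <- rowMeans(v[, as.vector(mask), drop = FALSE])
  post <- (stack$protocol$n_prestim + 1):d[1]
  dev <- tc[post] - 1
  dev[which.max(abs(dev))] * 100
}

#' Half-maximum footprint of the measured response
#'
#' Builds the response-amplitude map (mean deviation from 1 over the
#' response window) and returns the pixels whose absolute amplitude is at
#' least half the peak amplitude, together with their area. This is the
#' measured counterpart of [half_max_footprint()] and is the quantity the
#' recovery tests compare against the generator's closed form.
#'
#' @param stack a `normalized_stack`
#' @param response_window frame indices; same default as [t_map()]
#' @return list with `amplitude` (row x col map of fractional change),
#'   `mask`, `area_px`, `area_mm2`, `peak`
#' @export
response_footprint <- function(stack, response_window = NULL) {
  stopifnot(inherits(stack, "normalized_stack"))
  if (is.null(response_window))
    response_window <- stack$protocol$n_prestim +
      seq_len(min(16L, dim(stack$values)[1] - stack$protocol$n_prestim))
  d <- dim(stack$values)
  amp <- matrix(colMeans(matrix(stack$values[response_window, , ],
                                length(response_window), d[2] * d[3])) - 1,
                d[2], d[3])
  peak <- amp[which.max(abs(amp))]
  mask <- abs(amp) >= abs(peak) / 2 & sign(amp) == sign(peak)
  list(amplitude = amp, mask = mask, area_px = sum(mask),
       area_mm2 = sum(mask) * stack$protocol$pixel_size^2, peak = peak)
}

#' Fit the intensity-response relation
#'
#' Ordinary least squares of a response measure against the stimulation
#' light intensity: `y = a + b x` (`model = "linear"`, the usual choice
#' for activated area) or `y = a + b log(x)` (`model = "logarithmic"`, the
#' usual choice for peak reflectance change, which saturates). Reports the
#' coefficients, the determination coefficient R^2 and the overall F-test
#' p-value.
#'
#' @param x light intensities (mW/mm^2); at least 3, not all equal, and
#'   positive for the logarithmic model
#' @param y responses (areas in mm^2 or amplitudes in percent)
#' @param model `"linear"` or `"logarithmic"`
#' @return an object of class `intensity_fit`: `coefficients` (a, b),
#'   `r_squared`, `f_p`, `model`, and the underlying `lm` fit
#' @export
fit_intensity_response <- function(x, y, model = c("linear", "logarithmic")) {
  model <- match.arg(model)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3) stop("at least 3 points are required")
  if (diff(range(x)) == 0) stop("degenerate design: all x equal")
  if (model == "logarithmic" && any(x <= 0))
    stop("logarithmic model requires positive intensities")
  xr <- if (model == "logarithmic") log(x) else x
  fit <- lm(y ~ xr)
  s <- summary(fit)
  f_p <- if (is.null(s$fstatistic)) NA_real_ else
    unname(pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
              lower.tail = FALSE))
  structure(list(coefficients = stats::setNames(coef(fit), c("a", "b")),
                 r_squared = s$r.squared, f_p = f_p, model = model,
                 fit = fit),
            class = "intensity_fit")
}

#' @export
print.intensity_fit <- function(x, ...) {
  form <- if (x$model == "linear") "y = a + b*x" else "y = a + b*log(x)"
  cat(sprintf("Intensity-response fit (%s): %s\n", x$model, form))
  cat(sprintf("  a = %.4g, b = %.4g, R^2 = %.3f, F-test p = %.3g\n",
              x$coefficients[1], x$coefficients[2], x$r_squared, x$f_p))
  invisible(x)
}
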