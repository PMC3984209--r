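test_that("trial averaging and pre-stimulus normalization", {
  pr <- quick_protocol()
  # constant data normalize to exactly one
  tr0 <- quick_truth(peak_amplitude = 0)
  ns0 <- average_and_normalize(generate_trials(pr, tr0, seed = 1), "stim")
  expect_true(all(ns0$values == 1))

  # noise-free activation: center-pixel minimum equals 1 + peak amplitude
  tr <- quick_truth(peak_amplitude = -2.2e-4)
  ns <- average_and_normalize(generate_trials(pr, tr, seed = 1), "stim")
  pre <- matrix(ns$values[1:pr$n_prestim, , ], pr$n_prestim)
  expect_lt(max(abs(colMeans(pre) - 1)), 1e-12)
  expect_equal(min(ns$values), 0.99978, tolerance = 5e-6)

  # averaging N noisy trials shrinks pre-stimulus variance ~N-fold
  trn <- quick_truth(peak_amplitude = 0, noise_sigma = 5e-4)
  one <- generate_trials(quick_protocol(n_stim = 1L), trn, seed = 3)
  many <- generate_trials(quick_protocol(n_stim = 16L), trn, seed = 3)
  v1 <- var(as.vector(average_and_normalize(one, "stim")$values))
  v16 <- var(as.vector(average_and_normalize(many, "stim")$values))
  expect_gt(v1 / v16, 16 / 2)
  expect_lt(v1 / v16, 16 * 2)

  # idempotence: re-normalizing an already-normalized single trial
  again <- structure(list(
    data = array(ns$values, c(1, dim(ns$values))),
    condition = factor("stim", c("stim", "blank")),
    protocol = pr, truth = tr, seed = 0), class = "ioi_trials")
  ns2 <- average_and_normalize(again, "stim")
  expect_equal(ns2$values, ns$values, tolerance = 1e-12)
})

test_that("Gaussian spatial filter preserves DC and the kernel peak", {
  pr <- quick_protocol(shape = c(64L, 64L), n_stim = 1L, n_blank = 1L,
                       n_frames = 10L)
  tr <- quick_truth(center = c(32.5, 32.5), peak_amplitude = 0)
  ns <- average_and_normalize(generate_trials(pr, tr, seed = 1), "stim")

  expect_identical(spatial_filter(ns, 0)$values, ns$values)
  f <- spatial_filter(ns, 4)
  expect_equal(f$values, ns$values, tolerance = 1e-12)  # constant frames

  # unit impulse: center value = 1/(2 pi sigma^2)
  imp <- array(0, c(1, 65, 65))
  imp[1, 33, 33] <- 1
  sm <- spatial_filter(imp, 4)
  expect_equal(sm[1, 33, 33], 1 / (2 * pi * 16), tolerance = 1e-3)
  expect_equal(sum(sm), 1, tolerance = 1e-6)

  expect_error(spatial_filter(ns, -1), "sigma")
})

test_that("t-maps flag true activation and respect alpha nesting", {
  pr <- quick_protocol(n_stim = 8L, n_blank = 2L)
  tr <- quick_truth(peak_amplitude = -2.2e-4, noise_sigma = 2e-5)
  ns <- average_and_normalize(generate_trials(pr, tr, seed = 8), "stim")
  m <- t_map(ns, alpha = 0.01)
  # within-window variance includes the HRF ramp itself, so p is small
  # but not machine-zero
  expect_lt(m$p_map[24, 24], 1e-4)
  expect_true(m$mask[24, 24])
  # significant set grows with alpha
  m2 <- t_map(ns, alpha = 0.05)
  expect_true(all(m2$mask[m$mask]))
  expect_equal(m$area, sum(m$mask) * 0.01^2)
  expect_equal(activation_area(m), m$area)
  expect_equal(activation_area(m, pixel_size = 0.02), sum(m$mask) * 4e-4)

  # centroid of the detected region sits on the true center
  expect_lt(sqrt(sum((mask_centroid(m) - tr$center)^2)),
            2 * tr$spatial_sigma)

  expect_error(t_map(ns, response_window = 5:20), "disjoint")
  expect_error(t_map(ns, response_window = 12L), "2 frames")
})

test_that("type-I error is calibrated on unfiltered null data", {
  pr <- quick_protocol(shape = c(72L, 72L), n_stim = 2L, n_blank = 10L)
  tr <- quick_truth(noise_sigma = 1e-4, peak_amplitude = 0)
  ns <- average_and_normalize(generate_trials(pr, tr, seed = 12), "blank")
  m <- t_map(ns, alpha = 0.05)
  frac <- mean(m$mask)
  n <- prod(pr$image_shape)
  ci <- 0.05 + c(-1, 1) * 2.58 * sqrt(0.05 * 0.95 / n)
  # slightly widened for the Welch small-sample approximation
  expect_gt(frac, ci[1] - 0.01)
  expect_lt(frac, ci[2] + 0.01)
})

test_that("peak amplitude extraction averages the masked time course", {
  pr <- quick_protocol()
  tr0 <- quick_truth(peak_amplitude = 0)
  ns0 <- average_and_normalize(generate_trials(pr, tr0, seed = 1), "stim")
  full <- matrix(TRUE, 48, 48)
  expect_equal(peak_amplitude(ns0, full), 0)

  tr <- quick_truth(peak_amplitude = -2.2e-4)
  ns <- average_and_normalize(generate_trials(pr, tr, seed = 1), "stim")
  fp <- response_footprint(ns)
  # spatial mean of a unit-peak Gaussian over its half-max disc = 1/(2 ln 2)
  pk <- peak_amplitude(ns, fp$mask)
  expect_lt(pk, -0.022 / 2)   # between half and full amplitude, in %
  expect_gt(pk, -0.022)
  expect_equal(pk, -0.022 / (2 * log(2)), tolerance = 0.05)
  expect_lt(pk, 0)            # sign follows the generator

  expect_error(peak_amplitude(ns, matrix(FALSE, 48, 48)), "empty")
})

test_that("measured footprint recovers the generator closed form", {
  pr <- quick_protocol(shape = c(64L, 64L), n_stim = 10L, n_blank = 2L)
  tr <- quick_truth(center = c(32.5, 32.5), spatial_sigma = 9,
                    noise_sigma = 0)
  ns <- average_and_normalize(generate_trials(pr, tr, seed = 4), "stim")
  fp <- response_footprint(ns)
  truth_fp <- half_max_footprint(tr, pr$pixel_size)
  expect_equal(fp$area_px, truth_fp$area_px, tolerance = 0.05)
  expect_equal(fp$area_mm2, truth_fp$area_mm2, tolerance = 0.05)
  # footprint peak is the window-mean response: same sign, smaller than
  # the instantaneous peak amplitude
  expect_lt(fp$peak, 0)
  expect_gt(fp$peak, tr$peak_amplitude)
  expect_lt(fp$peak, tr$peak_amplitude * 0.3)
})

test_that("intensity-response fits recover exact and noisy relations", {
  x <- c(0.5, 1.4, 2.2, 3.2, 5, 8.9)
  lin <- fit_intensity_response(x, 0.3 + 0.45 * x, "linear")
  expect_equal(lin$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(lin$coefficients), c(0.3, 0.45), tolerance = 1e-10)
  expect_lt(lin$f_p, 1e-8)

  lg <- fit_intensity_response(x, -0.01 - 0.007 * log(x), "logarithmic")
  expect_equal(lg$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(lg$coefficients), c(-0.01, -0.007), tolerance = 1e-10)

  expect_error(fit_intensity_response(c(1, 2), c(1, 2)), "3 points")
  expect_error(fit_intensity_response(rep(2, 5), 1:5), "degenerate")
  expect_error(fit_intensity_response(c(-1, 1, 2), 1:3, "logarithmic"),
               "positive")

  # known-R^2 oracle: mean R^2 over seeds matches the noncentral-F
  # expectation for the design
  xs <- 1:9
  b <- 2
  rho2 <- 0.7
  sig2 <- b^2 * var(xs) * (1 - rho2) / rho2
  lambda <- b^2 * sum((xs - mean(xs))^2) / sig2
  dfd <- length(xs) - 2
  er2 <- integrate(function(f) f / (f + dfd) *
                     df(f, 1, dfd, ncp = lambda), 0, Inf,
                   rel.tol = 1e-9)$value
  set.seed(100)
  r2 <- replicate(150, {
    y <- 1 + b * xs + rnorm(9, sd = sqrt(sig2))
    fit_intensity_response(xs, y, "linear")$r_squared
  })
  expect_lt(abs(mean(r2) - er2), 3 * sd(r2) / sqrt(length(r2)))
})
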