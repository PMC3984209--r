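test_that("hemodynamic time course is causal, unimodal and scaled", {
  pr <- acquisition_protocol()
  tr <- ground_truth_activation()
  m <- hrf_timecourse(pr, tr)
  expect_length(m, 80)
  expect_identical(m[1:8], rep(1, 8))
  # peak frame: onset 2 s + 2.5 s at 4 Hz is exactly frame 19
  expect_equal(which.min(m), 19)
  expect_equal(min(m), 1 + tr$peak_amplitude)
  # returns toward baseline by trial end
  expect_lt(abs(m[80] - 1), abs(tr$peak_amplitude) / 10)

  m0 <- hrf_timecourse(pr, ground_truth_activation(peak_amplitude = 0))
  expect_identical(m0, rep(1, 80))

  # kernel width: crossings of half amplitude span ~hrf_width seconds
  tgrid <- seq_len(80)
  half <- which(m - 1 <= tr$peak_amplitude / 2)
  width_s <- (max(half) - min(half)) / pr$frame_rate
  expect_equal(width_s, tr$hrf_width, tolerance = 0.35)
})

test_that("trial generation is deterministic and leaves the RNG alone", {
  pr <- quick_protocol()
  tr <- quick_truth(noise_sigma = 1e-4)
  set.seed(777)
  before <- .Random.seed
  a <- generate_trials(pr, tr, seed = 5)
  expect_identical(.Random.seed, before)
  b <- generate_trials(pr, tr, seed = 5)
  expect_identical(a$data, b$data)
  expect_identical(a$condition, b$condition)
  expect_false(identical(a$data, generate_trials(pr, tr, seed = 6)$data))
  expect_equal(sum(a$condition == "stim"), 6)
  expect_equal(sum(a$condition == "blank"), 6)
  expect_true(all(a$data > 0))
})

test_that("noise-free trials equal their construction", {
  pr <- quick_protocol()
  tr <- quick_truth()   # noise_sigma = 0
  ts <- generate_trials(pr, tr, seed = 1)
  blank <- ts$data[which(ts$condition == "blank")[1], , , ]
  expect_true(all(blank == tr$baseline))

  tr0 <- quick_truth(peak_amplitude = 0)
  ts0 <- generate_trials(pr, tr0, seed = 1)
  expect_true(all(ts0$data == tr0$baseline))

  # pixel near the center at the peak frame follows the construction
  m <- hrf_timecourse(pr, tr)
  stim <- ts$data[which(ts$condition == "stim")[1], , , ]
  peak_f <- which.min(m)
  d2 <- sum((c(24, 24) - tr$center)^2)
  g24 <- exp(-d2 / (2 * tr$spatial_sigma^2))
  expect_equal(stim[peak_f, 24, 24],
               tr$baseline * (1 + (m[peak_f] - 1) * g24),
               tolerance = 1e-12)
  # and the most responsive pixels reach the full amplitude to < 1%
  expect_equal(min(stim) / tr$baseline, 1 + tr$peak_amplitude,
               tolerance = abs(tr$peak_amplitude) * 0.01)
})

test_that("noise level matches the requested sigma", {
  pr <- quick_protocol(n_stim = 20L, n_blank = 1L)
  tr <- quick_truth(noise_sigma = 1e-4, peak_amplitude = 0)
  ts <- generate_trials(pr, tr, seed = 42)
  stim <- which(ts$condition == "stim")
  pre <- ts$data[stim, 1:pr$n_prestim, 24, 24] / tr$baseline
  n <- length(pre)                   # 160 pre-stimulus samples
  s <- sd(pre)
  # chi-square bounds: at n = 160 the SD is within 30% of truth w.h.p.
  expect_gt(s, 0.7e-4)
  expect_lt(s, 1.3e-4)
})

test_that("half-maximum footprint has the closed-form area", {
  tr <- quick_truth(spatial_sigma = 8)
  fp <- half_max_footprint(tr, pixel_size = 0.01)
  expect_equal(fp$radius_px, 8 * sqrt(2 * log(2)))
  expect_equal(fp$area_px, 2 * pi * log(2) * 64)
  expect_equal(fp$area_mm2, fp$area_px * 1e-4)
})

test_that("trial stacks round-trip through TIFF + sidecar", {
  pr <- quick_protocol(shape = c(16L, 16L), n_stim = 2L, n_blank = 2L,
                       n_frames = 10L)
  tr <- quick_truth(center = c(8.5, 8.5), noise_sigma = 2e-4)
  ts <- generate_trials(pr, tr, seed = 9)
  dir <- file.path(tempdir(), "stackrt")
  write_stack(ts, dir)
  expect_length(list.files(dir, pattern = "\\.tif$"), 4)
  back <- read_stack(dir)
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  expect_equal(back$seed, 9)
  expect_identical(as.character(back$condition), as.character(ts$condition))
  expect_lt(max(abs(back$data - ts$data)), meta$scale$step + 1e-12)
  expect_equal(dim(back$data), c(4, 10, 16, 16))
  unlink(dir, recursive = TRUE)
})
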