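test_that("identical seeds give bitwise-identical fluence maps", {
  a <- quick_mc(n_photons = 1e4, seed = 99)
  b <- quick_mc(n_photons = 1e4, seed = 99)
  expect_identical(a$values, b$values)
  expect_identical(a$totals, b$totals)
  c <- quick_mc(n_photons = 1e4, seed = 100)
  expect_false(identical(a$values, c$values))
})

test_that("photon weight is conserved through the transport ledger", {
  fl <- quick_mc(n_photons = 2e4, seed = 7)
  expect_lt(fl$totals$max_balance_err, 1e-9)
  with(fl$totals, expect_lt(
    abs(deposited + escaped + rr_loss - rr_gain - fl$n_photons), 1e-6))
  expect_true(all(fl$values >= 0))
  expect_true(all(is.finite(fl$values)))
})

test_that("pure absorption reproduces the Beer-Lambert depth profile", {
  props <- optical_properties(mu_a = 1, mu_s = 0)
  g <- voxel_grid(c(40L, 40L, 100L), 0.01, origin = c(-0.2, -0.2, 0))
  src <- source_spec(center = c(0, 0, 1e-9), normal = c(0, 0, 1),
                     radius = 0.004, half_angle = 0)
  n <- 1e5
  fl <- run_mc(src, g, props, n_photons = n, seed = 13)
  dep <- apply(fl$values, 3, sum)           # proportional to layer weight
  dep <- dep / sum(dep)
  edges <- seq(0, 1, by = 0.01)
  p_layer <- exp(-props$mu_a * edges[-101]) - exp(-props$mu_a * edges[-1])
  p_layer <- p_layer / sum(p_layer)         # renormalize to photons in grid
  for (k in c(10, 50, 90))
    expect_lt(abs(dep[k] - p_layer[k]), 4 * sqrt(p_layer[k] / n))
})

test_that("single-photon propagation honors limiting cases", {
  g <- quick_grid()
  # no absorption: everything escapes, nothing deposits
  p0 <- optical_properties(mu_a = 0, mu_s = 5, g = 0.9)
  r <- propagate_photon(c(0, 0, 0), c(0, 0, 1), g, p0, seed = 3)
  expect_equal(r$deposited, 0)
  expect_equal(r$escaped, 1)
  expect_lt(r$balance_err, 1e-12)

  # absorbing medium: ledger closes for each photon
  p1 <- quick_props()
  for (s in 1:20) {
    r <- propagate_photon(c(0, 0, 0), c(0, 0, 1), g, p1, seed = s)
    expect_lt(r$balance_err, 1e-9)
    expect_equal(r$deposited + r$escaped + r$rr_loss - r$rr_gain, 1,
                 tolerance = 1e-9)
  }

  expect_error(propagate_photon(c(5, 0, 0), c(0, 0, 1), g, p1, seed = 1),
               "outside")
})

test_that("voxel estimates converge at the Monte-Carlo rate", {
  props <- quick_props()
  grid <- quick_grid(20L, 0.05)
  ns <- c(4e3, 1.6e4, 6.4e4)
  # index of a high-fluence voxel from a pilot run
  pilot <- run_mc(source_spec(), grid, props, n_photons = 2e4, seed = 1)
  idx <- which.max(pilot$values * (pilot$values < max(pilot$values)))
  sds <- sapply(ns, function(n) {
    v <- sapply(1:12, function(s) {
      fl <- run_mc(source_spec(), grid, props, n_photons = n,
                   seed = 1000 + s)
      fl$values[idx] * fl$source_fluence_per_exit  # un-normalized scale
    })
    sd(v) / mean(v)
  })
  expect_true(all(diff(sds) < 0))
  # 16x more photons quarter the relative SD; the band covers the
  # sampling noise of an SD estimated from 12 replicates
  expect_gt(sds[1] / sds[3], 1.8)
  expect_lt(sds[1] / sds[3], 9)
})

test_that("mu_a = 0 is rejected by the fluence estimator", {
  expect_error(run_mc(source_spec(), quick_grid(),
                      optical_properties(mu_a = 0, mu_s = 5), 100, seed = 1),
               "mu_a")
})

test_that("fluence maps round-trip through NIfTI + sidecar", {
  fl <- quick_mc(n_photons = 5e3, seed = 17)
  path <- file.path(tempdir(), "fl.nii.gz")
  write_fluence(fl, path)
  fl2 <- read_fluence(path)
  expect_equal(fl2$values, fl$values, tolerance = 1e-6)
  expect_equal(fl2$seed, fl$seed)
  expect_equal(fl2$n_photons, fl$n_photons)
  expect_equal(fl2$source_fluence_per_exit, fl$source_fluence_per_exit)
  expect_equal(fl2$grid$voxel_size, fl$grid$voxel_size)
  unlink(c(path, paste0(path, ".json")))
})
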