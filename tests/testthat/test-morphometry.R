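test_that("volume is exactly voxel count times voxel volume", {
  m <- hematoma_mask(array(1L, c(10, 10, 10)), spacing = c(1, 1, 1))
  expect_identical(compute_volume(m), 1000)
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  expect_equal(compute_volume(hematoma_mask(one, spacing = c(0.5, 0.5, 1))),
               0.25)
  m8000 <- hematoma_mask(array(1L, c(20, 20, 20)),
                         spacing = c(0.5, 0.5, 0.5))
  expect_identical(compute_volume(m8000) / 1000, 1)
  # property: exact for arbitrary masks at anisotropic spacing
  for (s in 1:5) {
    set.seed(s)
    dat <- array(as.integer(runif(6^3) > 0.6), c(6, 6, 6))
    dat[1] <- 1L  # nonempty
    mk <- hematoma_mask(dat, spacing = c(0.45, 0.45, 1))
    expect_identical(compute_volume(mk), sum(dat) * 0.45 * 0.45 * 1)
  }
})

test_that("degenerate masks are rejected across the morphometry surface", {
  empty <- hematoma_mask(array(0L, c(4, 4, 4)))
  vol <- flat_volume(empty)
  expect_error(compute_volume(empty), "empty")
  expect_error(compute_surface_area(empty), "empty")
  expect_error(compute_dcv(vol, empty), "empty")
  neg <- voxel_volume(array(-5, c(4, 4, 4)))
  full <- hematoma_mask(array(1L, c(4, 4, 4)))
  expect_error(compute_dcv(neg, full), "not positive")
})

test_that("SRI closed forms, scale invariance and input checks", {
  r <- 10
  expect_equal(compute_sri(4 / 3 * pi * r^3, 4 * pi * r^2), 100)
  s <- 17
  expect_equal(compute_sri(s^3, 6 * s^2), 100 * sqrt(pi / 6))
  v0 <- 1234; s0 <- 567
  expect_equal(compute_sri(8 * v0, 4 * s0), compute_sri(v0, s0))
  expect_error(compute_sri(-1, 10), "positive")
  expect_error(compute_sri(10, 0), "positive")
})

test_that("DCV matches the hand formula and its invariances", {
  m <- hematoma_mask(array(1L, c(5, 5, 5)))
  const <- flat_volume(m, 60)
  expect_equal(compute_dcv(const, m)$dcv, 0)

  two <- array(0L, c(3, 3, 1)); two[1:2, 1, 1] <- 1L
  mk <- hematoma_mask(two)
  hu <- array(0, c(3, 3, 1)); hu[1, 1, 1] <- 50; hu[2, 1, 1] <- 70
  d <- compute_dcv(voxel_volume(hu), mk)
  expect_equal(d$mean_hu, 60)
  expect_equal(d$sd_hu, sqrt(200))               # n-1 divisor
  expect_equal(d$dcv, 100 * sqrt(200) / 60, tolerance = 1e-12)

  set.seed(2)
  hu2 <- array(rnorm(5^3, 60, 8), c(5, 5, 5))
  v1 <- voxel_volume(hu2); mfull <- hematoma_mask(array(1L, c(5, 5, 5)))
  base <- compute_dcv(v1, mfull)
  doubled <- compute_dcv(voxel_volume(2 * hu2), mfull)
  expect_equal(doubled$dcv, base$dcv, tolerance = 1e-12)
  shifted <- compute_dcv(voxel_volume(hu2 + 10), mfull)
  expect_equal(shifted$dcv, 100 * base$sd_hu / (base$mean_hu + 10),
               tolerance = 1e-12)
  pop <- compute_dcv(v1, mfull, sd_divisor = "population")
  expect_equal(pop$sd_hu, base$sd_hu * sqrt((125 - 1) / 125))
})

test_that("measure_hematoma fields are mutually consistent", {
  m <- digital_sphere(6, 1)
  set.seed(3)
  vol <- voxel_volume(array(rnorm(length(m$data), 60, 6), dim(m$data)),
                      spacing = m$spacing)
  res <- measure_hematoma(vol, m)
  expect_equal(res$volume_mm3, res$n_voxels * prod(m$spacing))
  expect_equal(res$volume_ml, res$volume_mm3 / 1000)
  expect_equal(res$dcv, 100 * res$sd_hu / res$mean_hu)
  expect_equal(res$sri, compute_sri(res$volume_mm3, res$surface_area_mm2))
  expect_gt(res$sri, 0)
  expect_gte(res$dcv, 0)
})

test_that("largest-component filtering is optional and off by default", {
  dat <- array(0L, c(12, 12, 12))
  dat[2:6, 2:6, 2:6] <- 1L        # 125 voxels
  dat[9:10, 9:10, 9:10] <- 1L     # 8 voxels, disconnected
  m <- hematoma_mask(dat)
  expect_equal(sum(keep_largest_component(m)$data), 125L)
  vol <- flat_volume(m)
  as_given <- measure_hematoma(vol, m)
  filtered <- measure_hematoma(vol, m, largest_component = TRUE)
  expect_equal(as_given$n_voxels, 133L)
  expect_equal(filtered$n_voxels, 125L)
})

test_that("expansion calls use strict >6 mL / >33% thresholds", {
  expect_true(classify_expansion(20, 27)$expanded)     # +7 mL
  expect_true(classify_expansion(3, 4.1)$expanded)     # +36.7%
  expect_false(classify_expansion(30, 36)$expanded)    # +6 mL, +20%: neither
  expect_false(classify_expansion(18, 23.90)$expanded) # +32.8%, +5.9 mL
  expect_true(classify_expansion(18, 24.01)$expanded)  # +6.01 mL
  # monotone non-decreasing in follow-up volume
  f <- seq(10, 40, by = 0.25)
  calls <- classify_expansion(rep(20, length(f)), f)$expanded
  expect_true(all(diff(as.integer(calls)) >= 0))
  expect_error(classify_expansion(0, 5), "positive")
  expect_error(classify_expansion(-2, 5), "positive")
  expect_error(classify_expansion(10, -1), "non-negative")
})
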