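test_that("reference geometry reproduces sphere closed forms and converges", {
  sp <- phantom_spec(base_radius = 10, perturbation_amplitude = 0, seed = 1)
  rg <- reference_geometry(sp)
  expect_equal(rg$volume_mm3, 4 / 3 * pi * 1000, tolerance = 1e-3)
  expect_equal(rg$surface_area_mm2, 4 * pi * 100, tolerance = 1e-3)
  expect_equal(rg$sri, 100, tolerance = 1e-3)
  irr <- phantom_spec(base_radius = 12, perturbation_amplitude = 0.3,
                      seed = 5)
  a <- reference_geometry(irr)
  b <- reference_geometry(irr, n_theta = 1024, n_phi = 2048)
  expect_equal(b$volume_mm3, a$volume_mm3, tolerance = 1e-3)
  expect_equal(b$surface_area_mm2, a$surface_area_mm2, tolerance = 1e-3)
})

test_that("perturbed shapes obey the isoperimetric inequality", {
  for (s in 1:3) {
    rg <- reference_geometry(phantom_spec(base_radius = 10,
                                          perturbation_amplitude = 0.3,
                                          seed = s))
    sphere_area <- (36 * pi)^(1 / 3) * rg$volume_mm3^(2 / 3)
    expect_gt(rg$surface_area_mm2, sphere_area)
    expect_lt(rg$sri, 100)
  }
})

test_that("phantom generation is seed-deterministic with named streams", {
  sp <- phantom_spec(base_radius = 8, perturbation_amplitude = 0.2,
                     noise_sd = 5, spacing = c(1, 1, 1), seed = 11)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$mask$data, p2$mask$data)
  # changing the noise settings must not move the shape
  sp_noisier <- phantom_spec(base_radius = 8, perturbation_amplitude = 0.2,
                             noise_sd = 12, spacing = c(1, 1, 1), seed = 11)
  p3 <- generate_phantom(sp_noisier)
  expect_identical(p3$mask$data, p1$mask$data)
  expect_false(identical(p3$volume$data, p1$volume$data))
})

test_that("noise-free spherical phantom measures as a homogeneous sphere", {
  sp <- phantom_spec(base_radius = 15, perturbation_amplitude = 0,
                     noise_sd = 0, hypodense_blob_count = 0,
                     spacing = c(0.5, 0.5, 0.5), seed = 2)
  ph <- generate_phantom(sp)
  m <- measure_hematoma(ph$volume, ph$mask)
  expect_equal(m$sri, 100, tolerance = 0.02)
  expect_gte(m$sri, 98)
  expect_identical(m$dcv, 0)
})

test_that("invalid phantom specs are refused", {
  expect_error(phantom_spec(perturbation_amplitude = 1), "positive")
  expect_error(phantom_spec(base_radius = -3), "positive")
  expect_error(phantom_spec(noise_sd = -1), ">= 0")
})

test_that("measured geometry tracks the quadrature oracle", {
  for (s in 1:3) {
    spec <- phantom_spec(base_radius = 9, perturbation_amplitude = 0.25,
                         perturbation_degree = 4, noise_sd = 4,
                         spacing = c(0.5, 0.5, 0.5), seed = s)
    ph <- generate_phantom(spec)
    m <- measure_hematoma(ph$volume, ph$mask)
    expect_equal(m$volume_mm3, ph$reference$volume_mm3, tolerance = 0.02)
    expect_equal(m$surface_area_mm2, ph$reference$surface_area_mm2,
                 tolerance = 0.05)
  }
})

test_that("measured SRI decreases with irregularity, DCV grows with noise", {
  mean_sri <- function(amp) {
    mean(vapply(1:5, function(s) {
      ph <- generate_phantom(phantom_spec(base_radius = 10,
                                          perturbation_amplitude = amp,
                                          noise_sd = 0,
                                          spacing = c(1, 1, 1), seed = s))
      m <- measure_hematoma(ph$volume, ph$mask)
      m$sri
    }, numeric(1)))
  }
  expect_gt(mean_sri(0.05), mean_sri(0.35))

  dcv_at <- function(noise_sd, blobs = 0) {
    ph <- generate_phantom(phantom_spec(base_radius = 12,
                                        perturbation_amplitude = 0,
                                        noise_sd = noise_sd,
                                        hypodense_blob_count = blobs,
                                        spacing = c(1, 1, 1), seed = 4))
    measure_hematoma(ph$volume, ph$mask)$dcv
  }
  expect_gt(dcv_at(9), dcv_at(3))
  expect_gt(dcv_at(3, blobs = 3), dcv_at(3, blobs = 0))
  # law of large numbers: DCV -> 100 * sigma / mu
  expect_equal(dcv_at(12), 100 * 12 / 60, tolerance = 0.05)
})
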