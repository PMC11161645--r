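test_that("multizone equal-DOF partition reproduces the reference diameters", {
  d <- multizone_diameters(12, 3)
  expect_equal(d$diameters_rounded, c(6.0, 8.5, 10.4))
  expect_equal(d$diameters, 12 * sqrt(1:3 / 4), tolerance = 1e-12)
  expect_equal(d$diameters, c(6, 8.485281, 10.392305), tolerance = 1e-6)
  expect_equal(d$n_zones, 4L)
  # degenerate and single-layer cases
  d0 <- multizone_diameters(12, 0)
  expect_equal(d0$n_zones, 1L)
  expect_length(d0$diameters, 0)
  d1 <- multizone_diameters(12, 1)
  expect_equal(d1$diameters, 12 / sqrt(2), tolerance = 1e-12)
})

test_that("layer path difference and coherence length formulas", {
  expect_equal(path_difference(0.17, 0.5), 85)
  expect_equal(path_difference(0, 0.5), 0)
  expect_equal(path_difference(0.17, 1.0), 170)
  # fluorescence: ~524 nm centre, 40 nm band -> ~7 um, order 10 um,
  # far below the 85 um per-layer path difference
  cl <- coherence_length(0.524, 0.040)
  expect_equal(cl, 0.524^2 / 0.040)
  expect_lt(cl, path_difference(0.17, 0.5))
  expect_equal(coherence_length(0.524, 0.020), 2 * cl)
  expect_equal(coherence_length(1, 1), 1)
})

test_that("multizone zones share the same internal defocus-phase spread", {
  cfg <- test_config()
  d <- multizone_diameters(cfg$pupil_diameter, 3)
  g <- make_pupil_grid(cfg)
  psi <- psfengine:::defocus_rate(g, cfg)
  bounds <- c(0, d$diameters / cfg$pupil_diameter, 1)
  spreads <- vapply(1:4, function(j) {
    zone <- g$aperture & g$rho >= bounds[j] & g$rho <= bounds[j + 1]
    diff(range(psi[zone]))
  }, numeric(1))
  # equal-rho^2 zoning equalizes the defocus spread (up to the small
  # non-paraxial correction and pixelization)
  expect_lt(diff(range(spreads)) / mean(spreads), 0.1)
})

test_that("multizone PSF conserves energy and extends the depth of field", {
  cfg <- test_config()
  d <- multizone_diameters(12, 3)
  zg <- c(-20, 0, 20)
  mz <- multizone_psf(d, cfg, zg)
  expect_equal(apply(mz$values, 1, sum), rep(1, 3), tolerance = 1e-6)
  expect_true(all(mz$values >= 0))
  # one zone degenerates to the clear aperture
  st0 <- psf_stack(zero_mask(cfg), cfg, zg)
  mz1 <- multizone_psf(multizone_diameters(12, 0), cfg, zg)
  expect_equal(mz1$values, st0$values)
  # defocused on-axis intensity beats the clear aperture
  ctr <- dim(mz$values)[2] / 2 + 1
  expect_gt(mz$values[3, ctr, ctr], st0$values[3, ctr, ctr])
  expect_gt(mz$values[1, ctr, ctr], st0$values[1, ctr, ctr])
  # oversized designs are rejected
  expect_error(multizone_psf(multizone_diameters(14, 2), cfg, zg),
               "exceeds")
  bad <- multizone_diameters(12, 2)
  bad$diameters[2] <- 12.5
  expect_error(multizone_psf(bad, cfg, zg), "smaller")
})

test_that("optimizer contracts: zero iterations, determinism, monotone history", {
  cfg <- test_config(grid_n = 32)
  st0 <- optimize_settings(iterations = 0, z_range = c(-10, 10), n_z = 4,
                           seed = 5)
  r0 <- optimize_tetrapod(cfg, st0, noise_model())
  expect_equal(nrow(r0$history), 1L)
  expect_equal(r0$final_cost, r0$initial_cost)
  # iterations = 0 returns the initialization untouched
  set.seed(5)
  g <- make_pupil_grid(cfg)
  init <- wrap_phase(matrix(rnorm(32^2, sd = 0.5), 32) * g$aperture)
  expect_equal(r0$mask$phase, init)
  st <- optimize_settings(iterations = 15, z_range = c(-10, 10), n_z = 4,
                          seed = 5, record_every = 5)
  ra <- optimize_tetrapod(cfg, st, noise_model())
  rb <- optimize_tetrapod(cfg, st, noise_model())
  expect_identical(ra$mask$phase, rb$mask$phase)
  expect_true(all(diff(ra$history$cost) <= 0))
  expect_lte(ra$final_cost, ra$initial_cost)
  # supplied-mask initialization is honored
  st2 <- optimize_settings(iterations = 0, z_range = c(-10, 10), n_z = 4,
                           init = ra$mask)
  expect_equal(optimize_tetrapod(cfg, st2, noise_model())$mask$phase,
               ra$mask$phase)
})

test_that("EDOF designer contracts and stationary zero-phase start", {
  cfg <- test_config(grid_n = 32)
  st0 <- optimize_settings(iterations = 0, z_range = c(-10, 10), n_z = 4)
  r0 <- optimize_edof(cfg, st0)
  expect_equal(nrow(r0$history), 1L)
  # a zero mask is a stationary (symmetric) point: with a tiny axial
  # range and the in-focus width as target, descent stays at zero phase
  sig0 <- 0.21 * cfg$wavelength / cfg$na
  stz <- optimize_settings(iterations = 10, z_range = c(-0.1, 0.1), n_z = 2,
                           init = "zeros")
  rz <- optimize_edof(cfg, stz, target_sigma = sig0)
  expect_equal(max(abs(rz$mask$phase)), 0)
  st <- optimize_settings(iterations = 15, z_range = c(-10, 10), n_z = 4,
                          seed = 3, record_every = 5)
  ra <- optimize_edof(cfg, st)
  rb <- optimize_edof(cfg, st)
  expect_identical(ra$mask$phase, rb$mask$phase)
  expect_true(all(diff(ra$history$cost) <= 0))
})

test_that("the optimized tetrapod encodes depth and breaks focal symmetry", {
  cfg <- test_config()
  res <- tetrapod_fixture()
  expect_lt(res$final_cost, res$initial_cost)
  # mirrored defocus planes are distinguishable for the tetrapod ...
  stk <- psf_stack(res$mask, cfg, c(-10, 10), crop = 64)
  ncc <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_lt(ncc(stk$values[1, , ], stk$values[2, , ]), 0.95)
  # ... but not for the clear aperture
  st0 <- psf_stack(zero_mask(cfg), cfg, c(-10, 10), crop = 64)
  expect_gt(ncc(st0$values[1, , ], st0$values[2, , ]), 0.99)
})

test_that("phase-to-depth conversion is exact and invertible", {
  cfg <- test_config(grid_n = 32)
  m <- rough_mask(cfg)
  dm <- phase_to_depth(m, wavelength = 0.524, material_index = 1.46)
  expect_true(all(dm$depth >= 0))
  expect_true(all(dm$depth < 0.524 / 0.46))
  # full-wave phase approaches lambda/(n-1) depth
  mx <- phase_mask(matrix(2 * pi - 1e-9, 32, 32))
  dmx <- phase_to_depth(mx, 0.524, 1.46)
  expect_equal(max(dmx$depth), 0.524 / 0.46, tolerance = 1e-6)
  expect_equal(phase_to_depth(zero_mask(cfg), 0.524, 1.46)$depth,
               matrix(0, 32, 32))
  # round trip recovers the wrapped mask
  back <- depth_to_phase(dm)
  expect_equal(back$phase, m$phase, tolerance = 1e-9)
  expect_error(phase_to_depth(m, 0.524, material_index = 1), "exceed")
})
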