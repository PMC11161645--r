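test_that("log-likelihood closed forms and guards", {
  cfg <- test_config()
  m <- rough_mask(cfg)
  th <- emitter_state(z0 = 4)
  noise <- noise_model(photons = 2000, background = 5)
  mu <- noise$photons * psf_at(m, cfg, th, crop = 48) + noise$background
  img0 <- matrix(0, 48, 48)
  expect_equal(log_likelihood(img0, m, cfg, th, noise), -sum(mu))
  # linear in the counts: adding a constant c adds c * sum(log(mu))
  img <- matrix(rpois(48^2, 20), 48)
  l1 <- log_likelihood(img, m, cfg, th, noise)
  l2 <- log_likelihood(img + 3, m, cfg, th, noise)
  expect_equal(l2 - l1, 3 * sum(log(mu)))
  # the simulated PSF is strictly positive, so zero background is legal
  expect_true(is.finite(
    log_likelihood(img, m, cfg, th, noise_model(photons = 10, background = 0))))
  expect_error(log_likelihood(img - 100, m, cfg, th, noise))
})

test_that("simulated data is most likely near the true axial position", {
  cfg <- test_config()
  m <- tetrapod_fixture()$mask
  noise <- noise_model(photons = 5000, background = 10)
  th <- emitter_state(z0 = 6)
  mu <- noise$photons * psf_at(m, cfg, th, crop = 64) + noise$background
  z_cand <- seq(2, 10, by = 1)
  set.seed(99)
  avg <- rep(0, length(z_cand))
  for (d in 1:50) {
    img <- matrix(rpois(length(mu), mu), nrow(mu))
    avg <- avg + vapply(z_cand, function(z)
      log_likelihood(img, m, cfg, emitter_state(z0 = z), noise), numeric(1))
  }
  expect_lte(abs(z_cand[which.max(avg)] - 6), 1)
})

test_that("analytic PSF gradients conserve energy and match finite differences", {
  cfg <- test_config()
  m <- rough_mask(cfg)
  th <- emitter_state(z0 = 7)
  g <- psf_gradient(m, cfg, th)
  for (d in list(g$dx, g$dy, g$dz)) expect_lt(abs(sum(d)), 1e-5)
  fd <- function(f, h) (f(h) - f(-h)) / (2 * h)
  gx <- fd(function(h) psf_at(m, cfg, emitter_state(x0 = h, z0 = 7)), 0.01)
  gy <- fd(function(h) psf_at(m, cfg, emitter_state(y0 = h, z0 = 7)), 0.01)
  gz <- fd(function(h) psf_at(m, cfg, emitter_state(z0 = 7 + h)), 0.05)
  expect_lt(sqrt(sum((g$dx - gx)^2) / sum(gx^2)), 0.01)
  expect_lt(sqrt(sum((g$dy - gy)^2) / sum(gy^2)), 0.01)
  expect_lt(sqrt(sum((g$dz - gz)^2) / sum(gz^2)), 0.01)
  # clear aperture at focus: axial derivative vanishes (quadratic minimum)
  g0 <- psf_gradient(zero_mask(cfg), cfg, emitter_state())
  expect_lt(max(abs(g0$dz)), 1e-3 * max(abs(g0$dx)))
})

test_that("Fisher matrix is symmetric PSD and scales with photons", {
  cfg <- test_config()
  m <- rough_mask(cfg)
  th <- emitter_state(z0 = 5)
  f <- fisher_matrix(m, cfg, th, noise_model(photons = 1000, background = 3))
  expect_equal(f$q, t(f$q))
  expect_true(all(eigen(f$q, symmetric = TRUE)$values > -1e-8 * max(f$q)))
  # background = 0: Q is exactly linear in the photon count
  f1 <- fisher_matrix(m, cfg, th, noise_model(photons = 1000, background = 0))
  f2 <- fisher_matrix(m, cfg, th, noise_model(photons = 2000, background = 0))
  expect_equal(f2$q, 2 * f1$q, tolerance = 1e-12)
  # clear aperture at focus: no axial information, full lateral symmetry
  f0 <- fisher_matrix(zero_mask(cfg), cfg, emitter_state())
  expect_lt(f0$q[3, 3], 1e-6 * f0$q[1, 1])
  expect_equal(f0$q[1, 1], f0$q[2, 2], tolerance = 1e-6)
  expect_gt(f0$q[1, 1], 0)
})

test_that("CRLB inverts the information matrix with a sane singular policy", {
  fr <- structure(list(q = diag(c(4, 4, 1)), z = 0, singular = FALSE),
                  class = "fisher_result")
  v <- crlb(fr)
  expect_equal(as.numeric(v), c(0.25, 0.25, 1))
  expect_equal(attr(v, "precision"), sqrt(c(0.25, 0.25, 1)))
  # unobservable direction -> capped and flagged
  fr2 <- structure(list(q = diag(c(4, 4, 0)), z = 0, singular = FALSE),
                   class = "fisher_result")
  v2 <- crlb(fr2, cap = 100)
  expect_equal(as.numeric(v2), c(0.25, 0.25, 100))
  expect_equal(attr(v2, "saturated"), c(FALSE, FALSE, TRUE))
  # all-zero matrix: everything capped
  fr3 <- structure(list(q = matrix(0, 3, 3), z = 0, singular = TRUE),
                   class = "fisher_result")
  expect_equal(as.numeric(crlb(fr3, cap = 9)), c(9, 9, 9))
  # finite values above the cap are clipped and flagged
  fr4 <- structure(list(q = diag(c(4, 4, 1e-6)), z = 0, singular = FALSE),
                   class = "fisher_result")
  v4 <- crlb(fr4, cap = 100)
  expect_equal(as.numeric(v4)[3], 100)
  expect_true(attr(v4, "saturated")[3])
})

test_that("Gaussian-PSF lateral CRLB matches the closed form sigma^2/N", {
  # isotropic Gaussian "PSF" with analytic position derivatives pushed
  # through the same Fisher assembly as the optics model
  sigma <- 2; npx <- 61
  idx <- seq_len(npx) - (npx + 1) / 2
  X <- matrix(idx, npx, npx, byrow = TRUE)
  Y <- matrix(idx, npx, npx)
  G <- exp(-(X^2 + Y^2) / (2 * sigma^2))
  G <- G / sum(G)
  dGx <- G * X / sigma^2
  dGy <- G * Y / sigma^2
  noise <- noise_model(photons = 5000, background = 1e-12)
  f <- fisher_from_gradients(G, list(dGx, dGy, matrix(0, npx, npx)), noise)
  v <- crlb(f, cap = 1e6)
  expect_equal(as.numeric(v[1]), sigma^2 / noise$photons, tolerance = 0.05)
  expect_equal(as.numeric(v[2]), sigma^2 / noise$photons, tolerance = 0.05)
  expect_true(attr(v, "saturated")[3])
})

test_that("analytic Fisher agrees with the brute-force finite-difference oracle", {
  cfg <- test_config()
  m <- rough_mask(cfg)
  noise <- noise_model(photons = 5000, background = 10)
  for (z in c(0, 8)) {
    fa <- fisher_matrix(m, cfg, emitter_state(z0 = z), noise)
    fn <- fisher_matrix_fd(m, cfg, emitter_state(z0 = z), noise)
    expect_lt(norm(fa$q - fn$q, "F") / norm(fn$q, "F"), 0.01)
  }
})

test_that("CRLB scales as 1/photons and never improves with background", {
  cfg <- test_config()
  m <- rough_mask(cfg)
  th <- emitter_state(z0 = 5)
  v1 <- crlb(fisher_matrix(m, cfg, th, noise_model(1000, 0)))
  v2 <- crlb(fisher_matrix(m, cfg, th, noise_model(4000, 0)))
  expect_equal(as.numeric(v1) / 4, as.numeric(v2), tolerance = 1e-10)
  prev <- rep(0, 3)
  for (b in c(0, 5, 50)) {
    v <- as.numeric(crlb(fisher_matrix(m, cfg, th, noise_model(1000, b))))
    expect_true(all(v >= prev - 1e-12))
    prev <- v
  }
})

test_that("design cost samples midpoints and respects basic invariances", {
  cfg <- test_config()
  zg <- psfengine:::design_z_grid(c(-30, 30), 100)
  expect_equal(zg[1], -29.7)
  expect_equal(diff(zg)[1], 0.6)
  expect_equal(length(zg), 100)
  m <- rough_mask(cfg)
  pr <- design_cost(m, cfg, c(-10, 10), n_samples = 8)
  expect_equal(pr$cost, sum(pr$crlb))
  expect_equal(pr$cap, 400)
  # global phase offset leaves |FT|^2, hence the cost, unchanged
  m2 <- phase_mask(m$phase + 1.234)
  pr2 <- design_cost(m2, cfg, c(-10, 10), n_samples = 8)
  expect_equal(pr2$cost, pr$cost, tolerance = 1e-9)
  expect_error(design_cost(m, cfg, c(10, -10), n_samples = 8))
  df <- crlb_profile_table(pr)
  expect_named(df, c("z", "crlb_x", "crlb_y", "crlb_z",
                     "sat_x", "sat_y", "sat_z"))
})
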