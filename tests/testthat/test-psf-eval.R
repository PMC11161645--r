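make_gaussian_patch <- function(n, sigma_px, x0 = 0, y0 = 0, amp = 1,
                                offset = 0) {
  idx <- seq_len(n) - (n / 2 + 1)
  X <- matrix(idx, n, n, byrow = TRUE)
  Y <- matrix(idx, n, n)
  amp * exp(-((X - x0)^2 + (Y - y0)^2) / (2 * sigma_px^2)) + offset
}

test_that("the Gaussian fitter recovers noiseless widths without bias", {
  pitch <- 0.4367
  # includes 1.39 um, a typical compact-EDOF width
  for (sigma_um in c(0.5, 1.39, 2.5, 5)) {
    n <- max(48, 16 * ceiling(sigma_um / pitch))
    f <- fit_gaussian_width(make_gaussian_patch(n, sigma_um / pitch,
                                                amp = 800, offset = 10),
                            pixel_pitch = pitch)
    expect_true(f$fit_ok)
    expect_equal(f$sigma, sigma_um, tolerance = 0.01)
    # FWHM/sigma is the analytic constant ~2.3548
    expect_equal(f$fwhm / f$sigma, 2 * sqrt(2 * log(2)), tolerance = 1e-4)
  }
  # sub-pixel centre recovery
  f <- fit_gaussian_width(make_gaussian_patch(48, 3, x0 = 1.3, y0 = -0.7),
                          pixel_pitch = 1)
  expect_equal(f$x, 1.3, tolerance = 0.01)
  expect_equal(f$y, -0.7, tolerance = 0.01)
  # degenerate inputs are flagged, not errors
  expect_false(fit_gaussian_width(matrix(5, 20, 20))$fit_ok)
  expect_error(fit_gaussian_width(matrix(1, 4, 4)), "5x5")
})

test_that("width-vs-defocus of the clear aperture is symmetric and broadens", {
  cfg <- test_config()
  stk <- psf_stack(zero_mask(cfg), cfg, seq(-20, 20, by = 4), crop = 96)
  wc <- width_vs_defocus(stk)
  expect_s3_class(wc, "width_curve")
  expect_true(all(wc$fit_ok))
  half <- (nrow(wc) - 1) / 2
  for (k in seq_len(half)) {
    expect_equal(wc$sigma[k], wc$sigma[nrow(wc) + 1 - k], tolerance = 0.02)
  }
  expect_gt(wc$sigma[1], wc$sigma[half + 1])       # sigma(|z|=20) > sigma(0)
  # monotone nondecreasing away from focus (within fit noise)
  expect_true(all(diff(wc$sigma[(half + 1):nrow(wc)]) > -0.02))
})

test_that("DOF factor identities", {
  z <- seq(-10, 10, by = 2)
  mkcurve <- function(sig) {
    structure(data.frame(z = z, sigma = sig, fit_ok = TRUE),
              class = c("width_curve", "data.frame"))
  }
  a <- mkcurve(1 + 0.1 * abs(z))
  expect_equal(dof_factor(a, a), 1)
  b <- mkcurve(1 + 0.2 * abs(z))
  expect_equal(dof_factor(a, b) * dof_factor(b, a), 1)
  expect_equal(dof_factor(a, b, threshold_ratio = Inf), 1)
  flat <- mkcurve(rep(1, length(z)))
  expect_gt(dof_factor(flat, b), 1)
  # a span that never satisfies the threshold is flagged
  spiky <- mkcurve(c(1, rep(10, length(z) - 1)))
  expect_warning(dof_factor(spiky, b, threshold_ratio = 1.2), "degenerate")
  expect_error(dof_factor(a, mkcurve(rep(1, 3))[1:3, ]))
})

test_that("detection finds isolated beads and suppresses close pairs", {
  cfg <- test_config()
  m <- zero_mask(cfg)
  pos <- expand.grid(x = c(-24, 0, 24), y = c(-24, 0, 24))
  pos <- pos[1:10 %% 2 > -1, ][1:9, ]  # 9 well-separated beads
  em <- data.frame(x = pos$x + runif(9, -1, 1), y = pos$y + runif(9, -1, 1),
                   z = 0, photons = 20000)
  em <- rbind(em, data.frame(x = em$x[1] + 35, y = em$y[1] + 35, z = 0,
                             photons = 20000))  # 10th, in a corner
  scn <- scene(em, fov = c(90, 90), background = 1)
  img <- render_snapshot(scn, m, cfg)
  recs <- detect_and_localize(img, min_separation = 10,
                              intensity_threshold = 50)
  expect_equal(nrow(recs), 10L)
  dx <- attr(img, "pixel_pitch")
  err <- vapply(seq_len(nrow(recs)), function(i)
    min(sqrt((em$x - recs$x[i])^2 + (em$y - recs$y[i])^2)), numeric(1))
  expect_lt(max(err) / dx, 0.25)
  # blank image: no detections
  expect_equal(nrow(detect_and_localize(matrix(0, 64, 64),
                                        intensity_threshold = 1)), 0L)
  # two beads closer than min_separation collapse to one record
  s2 <- scene(data.frame(x = c(-1, 1), y = c(0, 0), z = 0,
                         photons = c(20000, 15000)),
              fov = c(40, 40), background = 1)
  i2 <- render_snapshot(s2, m, cfg)
  r2 <- detect_and_localize(i2, min_separation = 12,
                            intensity_threshold = 50)
  expect_equal(nrow(r2), 1L)
})

test_that("MLE localization recovers noiseless positions exactly", {
  cfg <- test_config()
  mask <- tetrapod_fixture()$mask
  noise <- noise_model(photons = 5000, background = 10)
  th <- emitter_state(x0 = 0.21, y0 = -0.13, z0 = 7.4)
  img <- noise$photons * psf_at(mask, cfg, th, crop = 64) + noise$background
  est <- mle_localize(img, mask, cfg, noise,
                      init = emitter_state(z0 = 6.5))
  expect_lt(abs(est$x0 - th$x0), 1e-3)
  expect_lt(abs(est$y0 - th$y0), 1e-3)
  expect_lt(abs(est$z0 - th$z0), 1e-2)
  expect_true(attr(est, "converged"))
  expect_true(is.finite(attr(est, "loglik")))
})

test_that("Richardson-Lucy: identity, flux conservation, sharpening", {
  cfg <- test_config()
  m <- zero_mask(cfg)
  s <- scene(data.frame(x = 0, y = 0, z = 6, photons = 20000),
             fov = c(40, 40), background = 2)
  img <- render_snapshot(s, m, cfg)
  n <- nrow(img)
  # delta kernel: output equals input for any iteration count
  delta <- matrix(0, n, n); delta[n / 2 + 1, n / 2 + 1] <- 1
  expect_equal(richardson_lucy(img, delta, 13), unclass(img),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(richardson_lucy(img, delta, 0), unclass(img),
               ignore_attr = TRUE)
  # flux conserved at every iteration
  ker <- psf_at(m, cfg, emitter_state(z0 = 6), crop = n)
  prev <- img
  for (it in 1:5) {
    cur <- richardson_lucy(img, ker, it)
    expect_equal(sum(cur), sum(img), tolerance = 1e-6)
    prev <- cur
  }
  # deblurring a noiseless defocused bead: peak grows, width shrinks
  dec <- richardson_lucy(img, ker, 50)
  expect_gt(max(dec), 2 * max(img))
  # width via background-subtracted second moment (the deconvolved
  # spike is narrower than the fitter's resolvable floor)
  mom_width <- function(im) {
    ctr <- nrow(im) / 2 + 1
    im <- im[(ctr - 12):(ctr + 12), (ctr - 12):(ctr + 12)]
    idx <- seq_len(nrow(im)) - 13
    w <- pmax(im - stats::median(im), 0)
    X <- matrix(idx, nrow(im), ncol(im), byrow = TRUE)
    Y <- t(X)
    sqrt(sum(w * (X^2 + Y^2)) / (2 * sum(w)))
  }
  expect_lt(mom_width(dec), 0.5 * mom_width(img))
  expect_error(richardson_lucy(img - 100, ker, 1), "nonnegative")
  expect_error(richardson_lucy(img, ker[1:10, 1:10], 1), "match")
})

test_that("ensemble MSD fitting recovers diffusion parameters", {
  # exact zero case
  tr0 <- simulate_brownian_tracks(
    track_sim_settings(n_particles = 3, diffusion_coeff = 0,
                       loc_noise_sigma = 0, n_frames = 20))
  r0 <- ensemble_msd_fit(tr0)
  expect_equal(unname(r0$d_est), rep(0, 3))
  expect_equal(unname(r0$s_est), rep(0, 3))
  # doubling all coordinates quadruples the MSD at every lag
  tr <- simulate_brownian_tracks(
    track_sim_settings(n_particles = 5, diffusion_coeff = 0.05,
                       loc_noise_sigma = 0.1, n_frames = 40, seed = 8))
  tr2 <- lapply(tr, function(t) { t$positions <- 2 * t$positions; t })
  m1 <- ensemble_msd_fit(tr)$msd
  m2 <- ensemble_msd_fit(tr2)$msd
  expect_equal(m2$msd_x, 4 * m1$msd_x, tolerance = 1e-12)
  expect_equal(m2$msd_z, 4 * m1$msd_z, tolerance = 1e-12)
  # parameter recovery at the reference scale (100 x 100 at 2.4 s)
  trr <- simulate_brownian_tracks(
    track_sim_settings(n_particles = 100, diffusion_coeff = 0.05,
                       dt = 2.4, n_frames = 100, loc_noise_sigma = 0.1,
                       seed = 21))
  rr <- ensemble_msd_fit(trr)
  expect_true(all(abs(rr$d_est - 0.05) / 0.05 < 0.10))
  expect_true(all(abs(rr$s_est - 0.1) / 0.1 < 0.25))
})
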