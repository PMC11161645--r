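#' Synthetic emitter scene
#'
#' A set of point emitters (fluorescent beads, nuclei, ...) in a 3D
#' volume, plus a uniform expected background. Coordinates are
#' sample-plane micrometres; x and y are centred on the optical axis, z
#' on the nominal focal plane.
#'
#' @param emitters Data frame with columns \code{x}, \code{y}, \code{z}
#'   (um) and \code{photons}.
#' @param fov Lateral field of view \code{c(width, height)} in um.
#' @param background Expected background photons per pixel.
#' @param label Free text.
#' @return An object of class \code{scene}.
#' @export
scene <- function(emitters, fov, background = 0, label = "") {
  emitters <- as.data.frame(emitters)
  stopifnot(all(c("x", "y", "z", "photons") %in% names(emitters)),
            length(fov) == 2, all(fov > 0), background >= 0)
  if (nrow(emitters) > 0) {
    stopifnot(all(emitters$photons >= 0),
              all(abs(emitters$x) <= fov[1] / 2),
              all(abs(emitters$y) <= fov[2] / 2))
  }
  structure(list(emitters = emitters, fov = as.numeric(fov),
                 background = background, label = label),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d emitters in %g x %g um FOV, background %g ph/px%s\n",
              nrow(x$emitters), x$fov[1], x$fov[2], x$background,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Random bead scene at a volumetric density
#'
#' Emulates fluorescent microspheres suspended in gel: the number of
#' beads is Poisson with mean \code{density * volume} and positions are
#' uniform in the volume. The default density of 22,000 beads per cubic
#' millimetre matches a dense bead-in-gel test sample.
#'
#' @param density Beads per cubic millimetre (>= 0).
#' @param volume Extents \code{c(x, y, z)} of the volume in micrometres,
#'   centred on the origin.
#' @param photons_mean Expected photons per bead.
#' @param background Expected background photons per pixel.
#' @param seed RNG seed (all randomness flows through it).
#' @return A \code{\link{scene}}.
#' @export
random_bead_scene <- function(density = 22000, volume = c(100, 100, 60),
                              photons_mean = 5000, background = 0, seed = 1) {
  stopifnot(density >= 0, length(volume) == 3, all(volume > 0))
  set.seed(seed)
  vol_mm3 <- prod(volume) * 1e-9           # um^3 -> mm^3
  n <- stats::rpois(1, density * vol_mm3)
  em <- data.frame(x = stats::runif(n, -volume[1] / 2, volume[1] / 2),
                   y = stats::runif(n, -volume[2] / 2, volume[2] / 2),
                   z = stats::runif(n, -volume[3] / 2, volume[3] / 2),
                   photons = rep(photons_mean, n))
  scene(em, fov = volume[1:2], background = background,
        label = sprintf("beads %g/mm^3", density))
}

#' Nuclei-on-a-shell spheroid fixture
#'
#' Qualitative stand-in for a labelled multicellular spheroid: emitters
#' are placed approximately uniformly on a spherical shell (nuclei of the
#' outer cell layer). No biological realism beyond the geometry is
#' claimed; intended for demos and end-to-end smoke tests.
#'
#' @param radius Shell radius in micrometres.
#' @param n_nuclei Number of emitters.
#' @param photons_mean Expected photons per nucleus.
#' @param background Background photons per pixel.
#' @param seed RNG seed.
#' @return A \code{\link{scene}} with fov \code{2.4 * radius} square.
#' @export
spheroid_shell_scene <- function(radius = 50, n_nuclei = 200,
                                 photons_mean = 5000, background = 0,
                                 seed = 1) {
  stopifnot(radius > 0, n_nuclei >= 0)
  set.seed(seed)
  u <- stats::runif(n_nuclei, -1, 1)        # cos(polar angle): uniform on sphere
  phi <- stats::runif(n_nuclei, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  em <- data.frame(x = radius * s * cos(phi), y = radius * s * sin(phi),
                   z = radius * u, photons = rep(photons_mean, n_nuclei))
  scene(em, fov = c(2.4, 2.4) * radius, background = background,
        label = "synthetic spheroid shell")
}

#' Render a camera snapshot of a scene
#'
#' Forward imaging: every emitter contributes
#' \code{photons * PSF(x, y, z - focal_offset)} with exact sub-pixel
#' placement (lateral position enters as a pupil phase ramp, never as
#' image-space interpolation), the uniform background is added, and the
#' result is optionally Poisson-sampled. The image grid is the FFT
#' sampling of the configuration (\code{\link{fourier_pixel_pitch}});
#' the canvas covers the scene's field of view.
#'
#' @param scn A \code{\link{scene}}.
#' @param mask A \code{\link{phase_mask}}.
#' @param config An \code{\link{optical_config}}.
#' @param focal_offset Focal-plane position in micrometres (a bead at
#'   \code{z} is defocused by \code{z - focal_offset}).
#' @param noise Logical: Poisson-sample the expected image.
#' @param seed RNG seed used when \code{noise} is \code{TRUE}.
#' @return Matrix of photon counts (noise on) or expected photons
#'   (noise off); rows are y, columns x; attribute \code{pixel_pitch}.
#' @export
render_snapshot <- function(scn, mask, config, focal_offset = 0,
                            noise = FALSE, seed = 1) {
  stopifnot(inherits(scn, "scene"))
  check_mask_config(mask, config)
  ctx <- pupil_ctx(config)
  img <- render_expected(ctx, scn, mask$phase, focal_offset)
  if (noise) {
    set.seed(seed)
    img <- matrix(stats::rpois(length(img), img), nrow(img), ncol(img))
  }
  attr(img, "pixel_pitch") <- ctx$dx
  img
}

# expected-photon canvas for a scene (no noise)
render_expected <- function(ctx, scn, mask_phase, focal_offset) {
  dx <- ctx$dx
  nx <- max(2L, 2L * ceiling(scn$fov[1] / dx / 2))
  ny <- max(2L, 2L * ceiling(scn$fov[2] / dx / 2))
  canvas <- matrix(scn$background, ny, nx)
  if (nrow(scn$emitters) == 0) return(canvas)
  N <- ctx$N
  for (k in seq_len(nrow(scn$emitters))) {
    e <- scn$emitters[k, ]
    # split lateral position into integer-pixel placement + sub-pixel shift
    px <- e$x / dx; py <- e$y / dx
    ix <- round(px); iy <- round(py)
    th <- emitter_state(x0 = (px - ix) * dx, y0 = (py - iy) * dx,
                        z0 = e$z - focal_offset)
    P <- psf_at_ctx(ctx, mask_phase, th)
    # PSF centre pixel (N/2+1, N/2+1) lands on canvas pixel
    # (ny/2+1+iy, nx/2+1+ix); add with clipping at the edges
    r0 <- ny / 2 + 1 + iy - (N / 2 + 1)   # row offset of PSF row 1
    c0 <- nx / 2 + 1 + ix - (N / 2 + 1)
    r_lo <- max(1, 1 + r0); r_hi <- min(ny, N + r0)
    c_lo <- max(1, 1 + c0); c_hi <- min(nx, N + c0)
    if (r_lo > r_hi || c_lo > c_hi) next
    rr <- r_lo:r_hi; cc <- c_lo:c_hi
    canvas[rr, cc] <- canvas[rr, cc] + e$photons * P[rr - r0, cc - c0]
  }
  canvas
}

#' Render a focal z-stack of a scene
#'
#' One \code{\link{render_snapshot}} per focal offset, emulating a
#' z-scan acquisition (e.g. 100 frames at 4 um steps for a 400 um
#' acquisition design). Noise seeds are derived per frame from
#' \code{seed} so frames are independent but the stack is reproducible.
#'
#' @inheritParams render_snapshot
#' @param z_positions Focal offsets in micrometres (nonempty).
#' @return 3D array (frame x y x x) with attributes \code{z_positions}
#'   and \code{pixel_pitch}.
#' @export
render_zstack <- function(scn, mask, config, z_positions, noise = FALSE,
                          seed = 1) {
  if (length(z_positions) == 0) stop("z_positions must be nonempty")
  frames <- lapply(seq_along(z_positions), function(k)
    render_snapshot(scn, mask, config, focal_offset = z_positions[k],
                    noise = noise, seed = seed + k - 1L))
  out <- array(0, dim = c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
  for (k in seq_along(frames)) out[k, , ] <- frames[[k]]
  attr(out, "z_positions") <- as.numeric(z_positions)
  attr(out, "pixel_pitch") <- attr(frames[[1]], "pixel_pitch")
  out
}

#' Settings for Brownian track simulation
#'
#' @param n_particles Number of particles.
#' @param diffusion_coeff Diffusion coefficient D in um^2/s.
#' @param dt Frame interval in seconds (default 2.4 s: a 0.4 s exposure
#'   plus a 2 s inter-frame delay, see \code{\link{nta_frame_period}}).
#' @param n_frames Frames per track.
#' @param loc_noise_sigma Per-axis localization noise s.d. in um.
#' @param seed RNG seed.
#' @return An object of class \code{track_sim_settings}.
#' @export
track_sim_settings <- function(n_particles = 100, diffusion_coeff = 0.05,
                               dt = 2.4, n_frames = 100,
                               loc_noise_sigma = 0.1, seed = 1) {
  stopifnot(n_particles >= 1, diffusion_coeff >= 0, dt > 0, n_frames >= 2,
            loc_noise_sigma >= 0)
  structure(list(n_particles = as.integer(n_particles),
                 diffusion_coeff = diffusion_coeff, dt = dt,
                 n_frames = as.integer(n_frames),
                 loc_noise_sigma = loc_noise_sigma, seed = as.integer(seed)),
            class = "track_sim_settings")
}

#' Frame period of a time-lapse acquisition
#'
#' The temporal resolution of a tracking acquisition is the exposure
#' time plus the inter-frame delay.
#'
#' @param exposure Exposure time in seconds.
#' @param delay Delay between frames in seconds.
#' @return Frame period in seconds.
#' @examples
#' nta_frame_period(0.4, 2.0)  # 2.4 s
#' @export
nta_frame_period <- function(exposure, delay) {
  stopifnot(exposure >= 0, delay >= 0)
  exposure + delay
}

#' Simulate 3D Brownian tracks with localization noise
#'
#' The standard nanoparticle-tracking model: per-axis increments are
#' independent zero-mean Gaussians of variance \code{2 * D * dt}, and
#' each recorded position carries independent Gaussian localization
#' noise of s.d. \code{loc_noise_sigma} per axis.
#'
#' @param settings A \code{\link{track_sim_settings}}.
#' @return List of tracks; each track is a list with \code{id},
#'   \code{times} (s), and \code{positions} (n_frames x 3 matrix, um).
#' @export
simulate_brownian_tracks <- function(settings = track_sim_settings()) {
  stopifnot(inherits(settings, "track_sim_settings"))
  set.seed(settings$seed)
  sd_step <- sqrt(2 * settings$diffusion_coeff * settings$dt)
  times <- (seq_len(settings$n_frames) - 1) * settings$dt
  lapply(seq_len(settings$n_particles), function(id) {
    steps <- matrix(stats::rnorm(3 * (settings$n_frames - 1), sd = sd_step),
                    ncol = 3)
    pos <- rbind(0, apply(steps, 2, cumsum))
    pos <- pos + matrix(stats::rnorm(3 * settings$n_frames,
                                     sd = settings$loc_noise_sigma), ncol = 3)
    colnames(pos) <- c("x", "y", "z")
    list(id = id, times = times, positions = pos)
  })
}
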