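#' Emitter state
#'
#' Position and brightness of a single point emitter: lateral position
#' (x0, y0) and axial position z0 relative to the nominal focal plane
#' (micrometres, sample-plane units), expected signal photons per frame,
#' and expected background photons per pixel.
#'
#' @param x0,y0,z0 Emitter position in micrometres.
#' @param photons Expected signal photon count (>= 0).
#' @param background Expected background photons per pixel (>= 0).
#' @return An object of class \code{emitter_state}.
#' @export
emitter_state <- function(x0 = 0, y0 = 0, z0 = 0, photons = 5000,
                          background = 10) {
  stopifnot(is.finite(x0), is.finite(y0), is.finite(z0),
            photons >= 0, background >= 0)
  structure(list(x0 = x0, y0 = y0, z0 = z0, photons = photons,
                 background = background),
            class = "emitter_state")
}

# ---- centred FFT helpers (even sizes only) ----------------------------------

# circular shift that moves the centre pixel (N/2+1, N/2+1) to (1,1);
# its own inverse for even N
ifftshift2 <- function(m) {
  n <- nrow(m)
  i <- c((n / 2 + 1):n, 1:(n / 2))
  m[i, i]
}

# centred forward DFT: U(m) = sum_p E(p) exp(-2*pi*i*p*m/N) with centred
# integer indices p, m; implemented as fftshift o fft o ifftshift
ftc <- function(m) ifftshift2(stats::fft(ifftshift2(m)))

# ---- pupil context ----------------------------------------------------------

# Precomputed per-config quantities shared by the PSF, Fisher and design
# code paths. All pupil-plane grids are grid_n x grid_n (centred); the
# transform plane is N x N with N = grid_n * pad_factor.
pupil_ctx <- function(config) {
  grid <- make_pupil_grid(config)
  n <- config$grid_n
  N <- n * config$pad_factor
  dx <- fourier_pixel_pitch(config)
  # phase ramp per micrometre of lateral shift: multiplying the pupil by
  # exp(i * px * 2*pi * d / N) shifts the image by d pixels
  cx <- 2 * pi * grid$px / (N * dx)
  cy <- 2 * pi * grid$py / (N * dx)
  psi <- defocus_rate(grid, config)
  emb <- seq.int(N / 2 - n / 2 + 1, N / 2 + n / 2)  # pupil rows/cols in padded
  list(config = config, grid = grid, n = n, N = N, dx = dx,
       cx = cx, cy = cy, psi = psi, emb = emb,
       # Parseval: sum |U|^2 = N^2 * sum |E|^2, with |E| = aperture
       norm = N^2 * sum(grid$aperture))
}

# embed an n x n pupil-plane matrix into the centred N x N padded plane
embed_pupil <- function(ctx, m) {
  out <- matrix(0 + 0i, ctx$N, ctx$N)
  out[ctx$emb, ctx$emb] <- m
  out
}

# complex pupil field for a mask and emitter state (n x n, centred)
pupil_field <- function(ctx, mask_phase, theta) {
  ph <- mask_phase + theta$z0 * ctx$psi
  if (theta$x0 != 0) ph <- ph + theta$x0 * ctx$cx
  if (theta$y0 != 0) ph <- ph + theta$y0 * ctx$cy
  ifelse(ctx$grid$aperture, exp(1i * ph), 0 + 0i)
}

# centred crop of an N x N plane to side m (both even)
crop_center <- function(img, m) {
  N <- nrow(img)
  if (m >= N) return(img)
  i <- seq.int(N / 2 - m / 2 + 1, N / 2 + m / 2)
  img[i, i]
}

# ---- PSF computation --------------------------------------------------------

#' Point-spread function of an emitter through a phase mask
#'
#' Scalar Fourier-optics forward model: the PSF is the squared modulus of
#' the Fourier transform of the pupil field
#' \code{aperture * exp(i * (mask + defocus(z0) + shift(x0, y0)))},
#' normalized so that the full (uncropped) transform plane sums to 1.
#' Lateral position is applied as a pupil phase ramp, so sub-pixel
#' placement is exact.
#'
#' @param mask A \code{\link{phase_mask}} on the config's pupil grid.
#' @param config An \code{\link{optical_config}}.
#' @param theta An \code{\link{emitter_state}} (photons/background are
#'   ignored here; the returned PSF is unit-normalized).
#' @param crop Optional even side length (pixels) of a centred crop;
#'   defaults to \code{config$fov_n} (full plane when \code{NULL}).
#' @return Matrix of nonnegative intensities (fraction of total photons
#'   per pixel); attribute \code{pixel_pitch} gives the sampling in
#'   micrometres.
#' @examples
#' cfg <- optical_config(grid_n = 64)
#' p <- psf_at(zero_mask(cfg), cfg, emitter_state())
#' sum(p)  # 1 up to numerical precision
#' @export
psf_at <- function(mask, config, theta = emitter_state(), crop = NULL) {
  check_mask_config(mask, config)
  ctx <- pupil_ctx(config)
  psf_at_ctx(ctx, mask$phase, theta, crop = crop %||% config$fov_n)
}

psf_at_ctx <- function(ctx, mask_phase, theta, crop = NULL) {
  E <- pupil_field(ctx, mask_phase, theta)
  U <- ftc(embed_pupil(ctx, E))
  P <- Re(U * Conj(U)) / ctx$norm
  if (!is.null(crop)) P <- crop_center(P, crop)
  attr(P, "pixel_pitch") <- ctx$dx
  P
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PSF stack across an axial grid
#'
#' Computes \code{\link{psf_at}} at \code{x0 = y0 = 0} for each axial
#' position, the simulated analogue of a bead z-scan.
#'
#' @param mask A \code{\link{phase_mask}}.
#' @param config An \code{\link{optical_config}}.
#' @param z_grid Strictly increasing axial positions in micrometres.
#' @param crop Optional centred crop side (pixels), default
#'   \code{config$fov_n}.
#' @return An object of class \code{psf_stack}: list with \code{values}
#'   (array z x y x x), \code{z_grid}, and \code{pixel_pitch} (um).
#' @export
psf_stack <- function(mask, config, z_grid, crop = NULL) {
  check_mask_config(mask, config)
  if (length(z_grid) == 0) stop("z_grid must be nonempty")
  if (is.unsorted(z_grid, strictly = TRUE))
    stop("z_grid must be strictly increasing")
  ctx <- pupil_ctx(config)
  crop <- crop %||% config$fov_n
  planes <- lapply(z_grid, function(z)
    psf_at_ctx(ctx, mask$phase, emitter_state(z0 = z), crop = crop))
  side <- nrow(planes[[1]])
  values <- array(0, dim = c(length(z_grid), side, side))
  for (k in seq_along(planes)) values[k, , ] <- planes[[k]]
  structure(list(values = values, z_grid = as.numeric(z_grid),
                 pixel_pitch = ctx$dx),
            class = "psf_stack")
}

#' @export
print.psf_stack <- function(x, ...) {
  cat(sprintf("<psf_stack> %d planes of %dx%d px (%.4f um/px), z in [%g, %g] um\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$pixel_pitch, min(x$z_grid), max(x$z_grid)))
  invisible(x)
}
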