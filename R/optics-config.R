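#' Optical system configuration
#'
#' Bundles the physical parameters of the imaging system used by every
#' simulation in the package: the numerical aperture and emission
#' wavelength set the diffraction scale, the pupil grid discretizes the
#' back focal plane (BFP), and the zero-padding factor sets the
#' sample-plane sampling of the simulated camera via the Fourier relation
#' \code{pitch = wavelength / (2 * na * pad_factor)}.
#'
#' Defaults correspond to a 10x / NA 0.3 objective in a high-throughput
#' live-cell imager with green emission (504--544 nm band, centre 524 nm)
#' and a 12 mm objective aperture. The camera pitch referred to the sample
#' plane (\code{pixel_pitch_sample}) is metadata: all simulations sample
#' the image on the grid implied by the FFT; \code{\link{check_sampling}}
#' warns when the supplied camera pitch disagrees with that grid.
#'
#' @param na Numerical aperture (dimensionless), must satisfy
#'   \code{0 < na < medium_index}.
#' @param wavelength Emission wavelength in micrometres.
#' @param magnification Lateral magnification (used only to refer camera
#'   quantities to the sample plane).
#' @param pupil_diameter Physical BFP aperture diameter in millimetres.
#' @param pixel_pitch_sample Optional camera pixel pitch referred to the
#'   sample plane (micrometres); \code{NULL} means "use the FFT-derived
#'   pitch" (the default, and what simulations always use internally).
#' @param medium_index Refractive index of the object space.
#' @param grid_n Side length of the pupil grid in pixels; even, >= 32.
#' @param pad_factor Zero-padding multiplier for the Fourier transform
#'   (>= 1); the padded transform side is \code{grid_n * pad_factor}.
#' @param fov_n Optional side length (pixels) to which PSFs are cropped;
#'   \code{NULL} keeps the full padded plane.
#'
#' @return An object of class \code{optical_config}.
#' @examples
#' cfg <- optical_config()
#' fourier_pixel_pitch(cfg)  # 0.524 / (2 * 0.3 * 2) = 0.4367 um
#' @export
optical_config <- function(na = 0.3, wavelength = 0.524, magnification = 10,
                           pupil_diameter = 12, pixel_pitch_sample = NULL,
                           medium_index = 1.0, grid_n = 128L, pad_factor = 2L,
                           fov_n = NULL) {
  grid_n <- as.integer(grid_n)
  if (grid_n < 32L || grid_n %% 2L != 0L)
    stop("grid_n must be even and >= 32, got ", grid_n)
  if (!is.numeric(na) || na <= 0 || na >= medium_index)
    stop("need 0 < na < medium_index (na = ", na,
         ", medium_index = ", medium_index, ")")
  if (wavelength <= 0) stop("wavelength must be positive")
  if (pad_factor < 1) stop("pad_factor must be >= 1")
  if (!is.null(fov_n)) {
    fov_n <- as.integer(fov_n)
    if (fov_n < 2L || fov_n > grid_n * pad_factor)
      stop("fov_n must lie in [2, grid_n * pad_factor]")
  }
  structure(list(na = na, wavelength = wavelength,
                 magnification = magnification,
                 pupil_diameter = pupil_diameter,
                 pixel_pitch_sample = pixel_pitch_sample,
                 medium_index = medium_index,
                 grid_n = grid_n, pad_factor = as.integer(pad_factor),
                 fov_n = fov_n),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  NA %.3g, lambda %.4g um, mag %gx, pupil %g mm, n(medium) %.3g\n",
              x$na, x$wavelength, x$magnification, x$pupil_diameter,
              x$medium_index))
  cat(sprintf("  pupil grid %d px, pad %dx -> image pitch %.4f um/px\n",
              x$grid_n, x$pad_factor, fourier_pixel_pitch(x)))
  invisible(x)
}

#' Sample-plane pixel pitch implied by the Fourier sampling
#'
#' The pupil grid spans spatial frequencies up to \code{na/wavelength}, so
#' the FFT output pixel is \code{wavelength / (2 * na * pad_factor)}
#' micrometres in the sample plane, independent of \code{grid_n}.
#'
#' @param config An \code{\link{optical_config}}.
#' @return Pixel pitch in micrometres per pixel.
#' @export
fourier_pixel_pitch <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  config$wavelength / (2 * config$na * config$pad_factor)
}

#' Check a user-supplied camera pitch against the simulation grid
#'
#' Simulations always sample the image on the FFT grid
#' (\code{\link{fourier_pixel_pitch}}). When the configuration carries a
#' camera-derived \code{pixel_pitch_sample} that differs from the FFT
#' pitch by more than \code{tol} (relative), a warning is issued so that
#' quantitative comparisons against camera data are made knowingly.
#'
#' @param config An \code{\link{optical_config}}.
#' @param tol Relative mismatch that triggers a warning (default 5\%).
#' @return Invisibly, the relative mismatch (0 when no pitch supplied).
#' @export
check_sampling <- function(config, tol = 0.05) {
  stopifnot(inherits(config, "optical_config"))
  if (is.null(config$pixel_pitch_sample)) return(invisible(0))
  fp <- fourier_pixel_pitch(config)
  mis <- abs(config$pixel_pitch_sample - fp) / fp
  if (mis > tol)
    warning(sprintf(paste0("camera pitch %.4f um differs from the FFT ",
                           "sampling %.4f um by %.1f%%; simulated images ",
                           "use the FFT grid"),
                    config$pixel_pitch_sample, fp, 100 * mis))
  invisible(mis)
}

#' Discretized back-focal-plane grid
#'
#' Builds the normalized pupil coordinates for a configuration: the
#' radial coordinate \code{rho} (1 on the aperture rim), the boolean
#' aperture support \code{rho <= 1}, and the transverse spatial-frequency
#' grids in 1/micrometre. The grid is centred between pixels
#' \code{grid_n/2} and \code{grid_n/2 + 1} (even-size FFT convention);
#' pixel \code{(grid_n/2 + 1, grid_n/2 + 1)} carries coordinate 0.
#'
#' @param config An \code{\link{optical_config}}.
#' @return An object of class \code{pupil_grid} with fields \code{rho},
#'   \code{aperture}, \code{kx}, \code{ky} (all \code{grid_n x grid_n};
#'   x varies along columns, y along rows) and the index vectors used to
#'   embed the pupil in the padded transform plane.
#' @export
make_pupil_grid <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  n <- config$grid_n
  p <- seq.int(-n / 2L, n / 2L - 1L)            # centred integer indices
  px <- matrix(p, n, n, byrow = TRUE)           # x along columns
  py <- matrix(p, n, n)                         # y along rows
  rho <- sqrt(px^2 + py^2) / (n / 2)
  dk <- 2 * (config$na / config$wavelength) / n # 1/um per pupil pixel
  structure(list(rho = rho, aperture = rho <= 1,
                 kx = px * dk, ky = py * dk, dk = dk,
                 px = px, py = py, n = n),
            class = "pupil_grid")
}

#' Defocus phase of a point source at axial position z
#'
#' Scalar-diffraction defocus term
#' \code{(2*pi/wavelength) * z * sqrt(medium_index^2 - na^2 * rho^2)}
#' evaluated on the aperture (zero outside). Exact (non-paraxial) form;
#' odd in \code{z}.
#'
#' @param grid A \code{\link{make_pupil_grid}} result.
#' @param config The matching \code{\link{optical_config}}.
#' @param z Axial position in micrometres (positive toward the objective).
#' @return A \code{grid_n x grid_n} matrix of phases in radians.
#' @export
defocus_phase <- function(grid, config, z) {
  stopifnot(inherits(grid, "pupil_grid"), inherits(config, "optical_config"),
            is.finite(z))
  z * defocus_rate(grid, config)
}

# Defocus phase per micrometre of z (radians/um on the aperture, 0 outside).
# The argument of sqrt is nonnegative on the aperture by the config
# invariant na < medium_index.
defocus_rate <- function(grid, config) {
  arg <- config$medium_index^2 - (config$na * grid$rho)^2
  psi <- (2 * pi / config$wavelength) * sqrt(pmax(arg, 0))
  psi * grid$aperture
}
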