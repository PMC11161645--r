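#' Phase mask on the pupil grid
#'
#' A phase mask is the design variable of PSF engineering: a grid of
#' optical phase values (radians) imposed in the back focal plane.
#' Values are stored wrapped to [0, 2*pi); wrapping is a no-op inside the
#' complex exponential, so all simulations are unaffected by it. Values
#' outside the aperture are carried but ignored by every operation.
#'
#' @param phase Square numeric matrix of phases in radians; all finite.
#' @param label Free-text identifier.
#' @return An object of class \code{phase_mask}.
#' @examples
#' m <- zero_mask(optical_config(grid_n = 64))
#' range(m$phase)
#' @export
phase_mask <- function(phase, label = "") {
  phase <- as.matrix(phase)
  if (nrow(phase) != ncol(phase)) stop("phase grid must be square")
  if (!all(is.finite(phase))) stop("phase values must all be finite")
  structure(list(phase = wrap_phase(phase), label = as.character(label)),
            class = "phase_mask")
}

#' The clear-aperture (zero-phase) mask
#'
#' @param config An \code{\link{optical_config}}; sets the grid size.
#' @return A \code{\link{phase_mask}} of zeros.
#' @export
zero_mask <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  phase_mask(matrix(0, config$grid_n, config$grid_n), label = "clear aperture")
}

#' Wrap phases to the canonical interval [0, 2*pi)
#'
#' @param phase Numeric vector or matrix of phases (radians).
#' @return Phases wrapped to [0, 2*pi), same shape.
#' @export
wrap_phase <- function(phase) {
  w <- phase %% (2 * pi)
  # x %% (2*pi) can return exactly 2*pi for tiny negative x
  w[w >= 2 * pi] <- 0
  w
}

#' @export
print.phase_mask <- function(x, ...) {
  cat(sprintf("<phase_mask> %dx%d px%s; phase range [%.3f, %.3f) rad\n",
              nrow(x$phase), ncol(x$phase),
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              min(x$phase), max(x$phase)))
  invisible(x)
}

# internal: validate a mask against a config
check_mask_config <- function(mask, config) {
  if (!inherits(mask, "phase_mask")) stop("not a phase_mask")
  if (nrow(mask$phase) != config$grid_n)
    stop(sprintf("mask grid (%d px) does not match config grid_n (%d px)",
                 nrow(mask$phase), config$grid_n))
  invisible(TRUE)
}
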