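#' Least-squares isotropic 2D Gaussian fit
#'
#' Fits \code{A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * sigma^2)) + b}
#' to an image patch by Nelder-Mead least squares from a moment-based
#' start. The reported FWHM is \code{2 * sqrt(2 * log(2)) * sigma}
#' (~2.355 sigma). Degenerate patches (no contrast, non-convergence,
#' width collapsing to the bounds) come back flagged rather than as
#' errors.
#'
#' @param patch Numeric matrix, at least 5x5 (rows y, columns x).
#' @param pixel_pitch Micrometres per pixel (1 = report in pixels).
#' @param min_r2 Minimum fraction of patch variance the fitted Gaussian
#'   must explain for the fit to count as ok (default 0.05); rejects
#'   "fits" that latch onto a speckle of a structureless plane.
#' @return List with \code{x}, \code{y} (um, relative to the patch
#'   centre), \code{sigma} (um), \code{fwhm}, \code{amplitude},
#'   \code{offset}, and \code{fit_ok}.
#' @export
fit_gaussian_width <- function(patch, pixel_pitch = 1, min_r2 = 0.05) {
  stopifnot(is.matrix(patch))
  if (nrow(patch) <= 5 || ncol(patch) <= 5)
    stop("patch must be larger than 5x5")
  ny <- nrow(patch); nx <- ncol(patch)
  xs <- (seq_len(nx) - (nx / 2 + 1))
  ys <- (seq_len(ny) - (ny / 2 + 1))
  bad <- list(x = NA_real_, y = NA_real_, sigma = NA_real_, fwhm = NA_real_,
              amplitude = NA_real_, offset = NA_real_, r2 = NA_real_,
              fit_ok = FALSE)
  b0 <- stats::median(patch)
  a0 <- max(patch) - b0
  if (!is.finite(a0) || a0 <= 0) return(bad)
  w <- pmax(patch - b0, 0)
  sw <- sum(w)
  if (sw <= 0) return(bad)
  x0 <- sum(t(w) * xs) / sw
  y0 <- sum(w * ys) / sw
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  s0 <- sqrt(max(sum(w * ((X - x0)^2 + (Y - y0)^2)) / (2 * sw), 0.25))
  obj <- function(p) {
    mdl <- p[4] * exp(-((X - p[1])^2 + (Y - p[2])^2) / (2 * p[3]^2)) + p[5]
    sum((patch - mdl)^2)
  }
  # Multi-start Nelder-Mead with restarts: PSFs with a narrow core on a
  # broad halo mislead the moment initialization (the fit latches onto
  # the halo), so narrow centred starts are tried as well
  run_from <- function(par) {
    for (attempt in 1:4) {
      fit <- tryCatch(
        stats::optim(par, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit) || fit$convergence == 0) return(fit)
      par <- fit$par
    }
    fit
  }
  peak <- which(patch == max(patch), arr.ind = TRUE)[1, ]
  starts <- list(c(x0, y0, s0, a0, b0),
                 c(xs[peak[2]], ys[peak[1]], 1.5, a0, b0),
                 c(xs[peak[2]], ys[peak[1]], 3, a0, b0))
  fit <- NULL
  for (st in starts) {
    f1 <- run_from(st)
    if (!is.null(f1) && (is.null(fit) || f1$value < fit$value)) fit <- f1
  }
  if (is.null(fit)) return(bad)
  p <- fit$par
  sig <- abs(p[3])
  # sanity: width must be resolvable and the peak must dominate the
  # residual structure
  ss_tot <- sum((patch - mean(patch))^2)
  r2 <- if (ss_tot > 0) 1 - fit$value / ss_tot else 0
  if (!is.finite(sig) || sig < 0.1 || sig > max(nx, ny) ||
      p[4] <= 0 || fit$convergence != 0 || r2 < min_r2)
    return(bad)
  list(x = p[1] * pixel_pitch, y = p[2] * pixel_pitch,
       sigma = sig * pixel_pitch,
       fwhm = 2 * sqrt(2 * log(2)) * sig * pixel_pitch,
       amplitude = p[4], offset = p[5], r2 = r2, fit_ok = TRUE)
}

#' PSF width as a function of defocus
#'
#' Fits an isotropic Gaussian to every plane of a PSF stack (at the
#' known on-axis centre) and returns the fitted standard deviation
#' versus axial position -- the broadening curve used to quantify depth
#' of field.
#'
#' @param stack A \code{psf_stack} (from \code{\link{psf_stack}} or
#'   \code{\link{multizone_psf}}).
#' @param patch_half Half-size of the central fit window in pixels
#'   (default 24 or the plane size, whichever is smaller).
#' @return An object of class \code{width_curve}: data frame with
#'   \code{z} (um), \code{sigma} (um), \code{fit_ok}.
#' @export
width_vs_defocus <- function(stack, patch_half = 24) {
  stopifnot(inherits(stack, "psf_stack"))
  n_z <- dim(stack$values)[1]
  side <- dim(stack$values)[2]
  h <- min(patch_half, side %/% 2 - 1)
  ctr <- side / 2 + 1
  rows <- (ctr - h):(ctr + h - 1)
  out <- data.frame(z = stack$z_grid, sigma = NA_real_, fit_ok = FALSE)
  for (k in seq_len(n_z)) {
    f <- fit_gaussian_width(stack$values[k, rows, rows],
                            pixel_pitch = stack$pixel_pitch)
    out$sigma[k] <- f$sigma
    out$fit_ok[k] <- f$fit_ok
  }
  class(out) <- c("width_curve", "data.frame")
  out
}

#' @export
plot.width_curve <- function(x, ...) {
  graphics::plot(x$z[x$fit_ok], x$sigma[x$fit_ok], type = "b",
                 xlab = "defocus z (um)", ylab = "fitted sigma (um)", ...)
  invisible(x)
}

# contiguous axial span (um) around the width minimum where
# sigma <= threshold_ratio * min(sigma); 0 when never satisfied
dof_span <- function(curve, threshold_ratio) {
  ok <- curve$fit_ok & is.finite(curve$sigma)
  if (!any(ok)) return(0)
  smin <- min(curve$sigma[ok])
  inside <- ok & curve$sigma <= threshold_ratio * smin
  if (!any(inside)) return(0)
  k0 <- which(ok)[which.min(curve$sigma[ok])]
  lo <- k0
  while (lo > 1 && inside[lo - 1]) lo <- lo - 1
  hi <- k0
  while (hi < nrow(curve) && inside[hi + 1]) hi <- hi + 1
  curve$z[hi] - curve$z[lo]
}

#' Depth-of-field improvement factor between two width curves
#'
#' The depth of field of a curve is operationalized as the contiguous
#' axial span around the width minimum over which
#' \code{sigma <= threshold_ratio * min(sigma)}. The factor is
#' \code{DOF(curve_a) / DOF(curve_b)}; an EDOF design evaluated against
#' the clear aperture should give a factor well above 1.
#'
#' @param curve_a,curve_b \code{width_curve}s sharing the same z grid.
#' @param threshold_ratio Width-tolerance ratio (default 1.5).
#' @return Scalar ratio; 0 or \code{Inf} (with a warning) when a span
#'   degenerates to zero.
#' @export
dof_factor <- function(curve_a, curve_b, threshold_ratio = 1.5) {
  stopifnot(inherits(curve_a, "width_curve"), inherits(curve_b, "width_curve"))
  if (!isTRUE(all.equal(curve_a$z, curve_b$z)))
    stop("curves must share the same z grid")
  a <- dof_span(curve_a, threshold_ratio)
  b <- dof_span(curve_b, threshold_ratio)
  if (b == 0 || a == 0)
    warning("degenerate DOF span (threshold never satisfied)")
  a / b
}

#' Detect and localize isolated emitters in an image
#'
#' Simple spot finder for well-separated emitters: local maxima above an
#' intensity threshold, non-maximum suppression within
#' \code{min_separation} pixels, then a Gaussian fit
#' (\code{\link{fit_gaussian_width}}) on a patch around each candidate.
#' Zero detections is a valid result.
#'
#' @param image Nonnegative matrix (rows y, columns x).
#' @param min_separation Minimum centre distance between detections, in
#'   pixels.
#' @param intensity_threshold Minimum peak value.
#' @param patch_half Half-size of the fit patch (pixels).
#' @param pixel_pitch Micrometres per pixel for the reported positions.
#' @return Data frame with columns \code{x}, \code{y} (um, origin at the
#'   image centre), \code{sigma} (um), \code{photons} (background-
#'   subtracted patch sum), \code{peak}, \code{fit_ok}.
#' @export
detect_and_localize <- function(image, min_separation = 8,
                                intensity_threshold = 0, patch_half = 8,
                                pixel_pitch = attr(image, "pixel_pitch") %||% 1) {
  stopifnot(is.matrix(image), all(image >= 0))
  ny <- nrow(image); nx <- ncol(image)
  r <- max(1L, as.integer(ceiling(min_separation)))
  cand <- which(image > intensity_threshold, arr.ind = TRUE)
  empty <- data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                      photons = numeric(0), peak = numeric(0),
                      fit_ok = logical(0))
  if (nrow(cand) == 0) return(empty)
  # keep candidates that are the strict max of their neighbourhood
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    nb <- image[max(1, i - r):min(ny, i + r), max(1, j - r):min(nx, j + r)]
    keep[k] <- image[i, j] == max(nb) &&
      sum(nb == max(nb)) == 1  # ignore plateaus
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  # greedy non-maximum suppression by brightness
  ord <- order(image[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  sel <- rep(TRUE, nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!sel[k]) next
    if (k < nrow(cand)) {
      d2 <- (cand[-(1:k), 1] - cand[k, 1])^2 + (cand[-(1:k), 2] - cand[k, 2])^2
      sel[-(1:k)][d2 < min_separation^2] <- FALSE
    }
  }
  cand <- cand[sel, , drop = FALSE]
  recs <- lapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    h <- patch_half
    rr <- max(1, i - h):min(ny, i + h)
    cc <- max(1, j - h):min(nx, j + h)
    patch <- image[rr, cc]
    if (nrow(patch) <= 5 || ncol(patch) <= 5)
      return(NULL)
    f <- fit_gaussian_width(patch, pixel_pitch = 1)
    # patch-centre pixel in the moment/fit coordinate system
    pc_y <- nrow(patch) / 2 + 1; pc_x <- ncol(patch) / 2 + 1
    off <- if (f$fit_ok) f$offset else stats::median(patch)
    data.frame(
      x = ((cc[1] + pc_x - 1 + (f$x %||% NA_real_)) - (nx / 2 + 1)) * pixel_pitch,
      y = ((rr[1] + pc_y - 1 + (f$y %||% NA_real_)) - (ny / 2 + 1)) * pixel_pitch,
      sigma = (f$sigma %||% NA_real_) * pixel_pitch,
      photons = sum(patch - off),
      peak = image[i, j],
      fit_ok = isTRUE(f$fit_ok))
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) empty else out
}

#' Maximum-likelihood localization of a single emitter
#'
#' Numerically maximizes the Poisson log-likelihood
#' (\code{\link{log_likelihood}}) over (x0, y0, z0) with a
#' derivative-free Nelder-Mead simplex, optionally multi-started over a
#' grid of axial initializations (the likelihood of symmetric PSFs is
#' bimodal in z).
#'
#' @param image Photon-count matrix (centred on the candidate emitter).
#' @param mask,config Forward model.
#' @param noise A \code{\link{noise_model}} (photons and background
#'   assumed known).
#' @param init An \code{\link{emitter_state}} initialization.
#' @param z_starts Optional numeric vector of additional z
#'   initializations for multi-start.
#' @return An \code{\link{emitter_state}} with attributes
#'   \code{loglik} and \code{converged}.
#' @export
mle_localize <- function(image, mask, config, noise, init = emitter_state(),
                         z_starts = NULL) {
  stopifnot(is.matrix(image))
  negll <- function(p) {
    th <- emitter_state(p[1], p[2], p[3])
    -log_likelihood(image, mask, config, th, noise)
  }
  starts <- list(c(init$x0, init$y0, init$z0))
  for (z in z_starts) starts <- c(starts, list(c(init$x0, init$y0, z)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negll, method = "Nelder-Mead",
                   control = list(maxit = 800, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("likelihood could not be evaluated at any start")
  est <- emitter_state(best$par[1], best$par[2], best$par[3],
                       photons = noise$photons, background = noise$background)
  attr(est, "loglik") <- -best$value
  attr(est, "converged") <- best$convergence == 0
  est
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative Richardson-Lucy update for Poisson-noise
#' images,
#' \code{est <- est * conv(flip(K), img / conv(K, est))},
#' with circular (FFT) convolution and the kernel centred on its grid.
#' With a unit-sum kernel the total flux is conserved exactly at every
#' iteration; \code{iterations = 0} returns the input.
#'
#' @param image Nonnegative matrix.
#' @param psf_kernel Nonnegative matrix, same size as \code{image},
#'   centred at pixel \code{(n/2 + 1, n/2 + 1)}; normalized to unit sum
#'   internally.
#' @param iterations Number of RL iterations (>= 0).
#' @return Deconvolved matrix, same size as the input.
#' @export
richardson_lucy <- function(image, psf_kernel, iterations) {
  stopifnot(is.matrix(image), is.matrix(psf_kernel), iterations >= 0)
  if (any(image < 0) || any(psf_kernel < 0))
    stop("image and kernel must be nonnegative")
  if (!all(dim(image) == dim(psf_kernel)))
    stop("kernel must match the image size")
  psf_kernel <- psf_kernel / sum(psf_kernel)
  K <- stats::fft(ifftshift2_rect(psf_kernel))
  Kc <- Conj(K)
  npx <- length(image)
  conv <- function(x, ker) Re(stats::fft(stats::fft(x) * ker, inverse = TRUE)) / npx
  est <- image
  eps <- .Machine$double.eps
  for (it in seq_len(iterations)) {
    denom <- pmax(conv(est, K), eps)
    est <- est * conv(image / denom, Kc)
    est[est < 0] <- 0
  }
  est
}

# ifftshift for possibly non-square (even-sized) matrices
ifftshift2_rect <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c((nr %/% 2 + 1):nr, 1:(nr %/% 2))
  ci <- c((nc %/% 2 + 1):nc, 1:(nc %/% 2))
  m[ri, ci]
}

#' Ensemble mean-square displacement and diffusion fit
#'
#' Per-axis ensemble MSD over lag times (averaging over all tracks and
#' time origins) followed by an inverse-variance-weighted linear fit of
#' \code{MSD(tau) = 2 * D * tau + 2 * s^2}: the slope gives the
#' diffusion coefficient D, the intercept the static localization
#' precision s (floored at zero, with a flag, when the fitted intercept
#' is negative). MSD values at different lags share the same underlying
#' displacements and are strongly correlated, so with enough tracks the
#' fit is generalized least squares with the full between-lag covariance
#' estimated by bootstrap over tracks; with fewer than 20 tracks it
#' falls back to diagonal inverse-variance weights. The bootstrap uses
#' an internal fixed seed and leaves the caller's RNG state untouched.
#'
#' @param tracks List of tracks as produced by
#'   \code{\link{simulate_brownian_tracks}}.
#' @param max_lag Largest lag time to use, in seconds (default: 10
#'   frames).
#' @param n_boot Track-bootstrap replicates for the GLS covariance
#'   (default 100).
#' @return An object of class \code{msd_result}: data frame \code{msd}
#'   (lag + per-axis MSD), vectors \code{d_est}, \code{s_est} (per axis:
#'   x, y, z), and \code{s_floored} flags.
#' @export
ensemble_msd_fit <- function(tracks, max_lag = NULL, n_boot = 100) {
  stopifnot(length(tracks) >= 1)
  dt <- diff(tracks[[1]]$times[1:2])
  n_frames <- min(vapply(tracks, function(tr) length(tr$times), integer(1)))
  max_lag_frames <- if (is.null(max_lag)) min(10L, n_frames - 1L)
  else max(1L, min(n_frames - 1L, floor(max_lag / dt)))
  lags <- seq_len(max_lag_frames)
  msd_of <- function(trs, ax) {
    vapply(lags, function(L) {
      mean(unlist(lapply(trs, function(tr) {
        p <- tr$positions[, ax]
        n <- length(p)
        if (n <= L) return(numeric(0))
        (p[(1 + L):n] - p[1:(n - L)])^2
      })))
    }, numeric(1))
  }
  tau <- lags * dt
  nlag <- length(lags)
  msd <- matrix(NA_real_, nlag, 3, dimnames = list(NULL, c("x", "y", "z")))
  d_est <- s_est <- numeric(3)
  floored <- logical(3)
  M <- length(tracks)
  use_gls <- M >= 20 && nlag >= 2
  if (use_gls) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(20240601L)
    boot_idx <- matrix(sample.int(M, M * n_boot, replace = TRUE), ncol = n_boot)
  }
  X <- cbind(1, tau)
  for (ax in 1:3) {
    y <- msd_of(tracks, ax)
    msd[, ax] <- y
    if (all(y == 0)) { d_est[ax] <- 0; s_est[ax] <- 0; next }
    if (use_gls) {
      B <- t(vapply(seq_len(n_boot), function(b)
        msd_of(tracks[boot_idx[, b]], ax), numeric(nlag)))
      S <- stats::cov(B) + diag(1e-12 * max(y)^2, nlag)
      W <- solve(S)
      beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
    } else {
      w <- 1 / pmax(y^2 * (2 * lags^2 + 1) /
                      (3 * lags * (n_frames - lags + 1)) / M, 1e-300)
      fit <- stats::lm(y ~ tau, weights = w)
      beta <- stats::coef(fit)
    }
    d_est[ax] <- beta[2] / 2
    floored[ax] <- beta[1] < 0
    s_est[ax] <- sqrt(max(beta[1], 0) / 2)
  }
  names(d_est) <- names(s_est) <- names(floored) <- c("x", "y", "z")
  structure(list(msd = data.frame(lag = tau, msd_x = msd[, 1],
                                  msd_y = msd[, 2], msd_z = msd[, 3]),
                 d_est = d_est, s_est = s_est, s_floored = floored),
            class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  cat("<msd_result>\n  D (um^2/s):", sprintf("%.4g", x$d_est), "\n")
  cat("  s (um):    ", sprintf("%.4g", x$s_est), "\n")
  invisible(x)
}
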