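#' Poisson noise model for localization analysis
#'
#' The detector is assumed shot-noise limited: each pixel is an
#' independent Poisson count with mean
#' \code{photons * PSF + background}, where the per-pixel background is
#' simplified to a single scalar. Defaults (5000 signal photons, 10
#' background photons/pixel) represent realistic single-molecule-scale
#' signal levels and are fully configurable.
#'
#' @param photons Expected signal photons per frame (> 0).
#' @param background Scalar expected background photons per pixel (>= 0).
#' @return An object of class \code{noise_model}.
#' @export
noise_model <- function(photons = 5000, background = 10) {
  stopifnot(photons > 0, background >= 0)
  structure(list(photons = photons, background = background),
            class = "noise_model")
}

#' Poisson log-likelihood of an image given an emitter state
#'
#' Returns \code{sum(I * log(mu) - mu)} with
#' \code{mu = photons * PSF(theta) + background}. The additive term that
#' depends only on the data (the log-factorial) is omitted: it is
#' constant in the emitter parameters and cancels in gradients and in the
#' Fisher information.
#'
#' @param image Nonnegative photon-count matrix; the model PSF is cropped
#'   centrally to its size.
#' @param mask,config Forward model (\code{\link{phase_mask}},
#'   \code{\link{optical_config}}).
#' @param theta An \code{\link{emitter_state}} (position only is used).
#' @param noise A \code{\link{noise_model}}.
#' @return Scalar log-likelihood (up to the data-only constant).
#' @export
log_likelihood <- function(image, mask, config, theta, noise) {
  stopifnot(is.matrix(image), all(image >= 0))
  P <- psf_at(mask, config, theta, crop = nrow(image))
  if (!all(dim(P) == dim(image)))
    stop("image is larger than the simulated plane")
  mu <- noise$photons * P + noise$background
  if (any(mu <= 0))
    stop("expected image has non-positive pixels; use background > 0 ",
         "so the Poisson mean is strictly positive everywhere")
  sum(image * log(mu) - mu)
}

#' Analytic PSF gradients with respect to emitter position
#'
#' Derivatives of the unit-normalized PSF with respect to (x0, y0, z0),
#' computed exactly through the Fourier model: lateral derivatives from
#' the pupil shift ramp, the axial derivative from the defocus rate.
#' Each gradient plane sums to ~0 because the total PSF energy does not
#' depend on the emitter position.
#'
#' @inheritParams log_likelihood
#' @param crop Optional centred crop side (pixels), default
#'   \code{config$fov_n}.
#' @return List with matrices \code{dx}, \code{dy}, \code{dz}
#'   (units 1/um per pixel) and the PSF itself as \code{psf}.
#' @export
psf_gradient <- function(mask, config, theta = emitter_state(), crop = NULL) {
  check_mask_config(mask, config)
  ctx <- pupil_ctx(config)
  g <- psf_gradient_ctx(ctx, mask$phase, theta)
  crop <- crop %||% config$fov_n
  if (!is.null(crop)) g <- lapply(g, crop_center, m = crop)
  g
}

# core gradient computation on a pupil context; returns full-plane grids
# and (optionally, keep_fields) the complex intermediates for backprop
psf_gradient_ctx <- function(ctx, mask_phase, theta, keep_fields = FALSE) {
  E <- pupil_field(ctx, mask_phase, theta)
  U <- ftc(embed_pupil(ctx, E))
  Vx <- ftc(embed_pupil(ctx, 1i * ctx$cx * E))
  Vy <- ftc(embed_pupil(ctx, 1i * ctx$cy * E))
  Vz <- ftc(embed_pupil(ctx, 1i * ctx$psi * E))
  S <- ctx$norm
  out <- list(psf = Re(U * Conj(U)) / S,
              dx = 2 * Re(Conj(U) * Vx) / S,
              dy = 2 * Re(Conj(U) * Vy) / S,
              dz = 2 * Re(Conj(U) * Vz) / S)
  if (keep_fields) {
    out$E <- E; out$U <- U; out$V <- list(x = Vx, y = Vy, z = Vz)
  }
  out
}

#' Fisher information matrix for 3D localization under Poisson noise
#'
#' For pixelwise-independent Poisson counts with mean
#' \code{mu = photons * PSF + background}, the Fisher information for the
#' position parameters (x0, y0, z0) is
#' \deqn{Q_{ij} = \sum_{pixels} \frac{(N \partial_i PSF)(N \partial_j PSF)}
#'   {N\,PSF + B}.}
#' Computed from the analytic gradients of \code{\link{psf_gradient}}.
#'
#' @inheritParams psf_gradient
#' @param noise A \code{\link{noise_model}}.
#' @return An object of class \code{fisher_result}: \code{q} (3x3,
#'   photons/um^2), \code{z} (axial position of evaluation), and
#'   \code{singular} (TRUE when all gradients vanish).
#' @export
fisher_matrix <- function(mask, config, theta = emitter_state(),
                          noise = noise_model(), crop = NULL) {
  check_mask_config(mask, config)
  ctx <- pupil_ctx(config)
  fisher_matrix_ctx(ctx, mask$phase, theta, noise, crop = crop %||% config$fov_n)
}

fisher_matrix_ctx <- function(ctx, mask_phase, theta, noise, crop = NULL,
                              grads = NULL) {
  g <- grads %||% psf_gradient_ctx(ctx, mask_phase, theta)
  pl <- list(g$dx, g$dy, g$dz)
  P <- g$psf
  if (!is.null(crop)) {
    pl <- lapply(pl, crop_center, m = crop)
    P <- crop_center(P, crop)
  }
  fisher_from_gradients(P, pl, noise, z = theta$z0)
}

#' Assemble the Poisson Fisher matrix from a PSF and its gradients
#'
#' The pixel-sum quotient at the heart of the localization bound:
#' \code{Q[i,j] = sum((photons * dPSF_i) * (photons * dPSF_j) /
#' (photons * PSF + background))}. Exposed so that closed-form PSF
#' models (e.g. an isotropic Gaussian, whose lateral CRLB is
#' \code{sigma^2 / N}) can be pushed through the same machinery as the
#' Fourier-optics model.
#'
#' @param psf Unit-normalized PSF matrix.
#' @param grads List of three matrices: the PSF derivatives with respect
#'   to x0, y0, z0 (units 1/um per pixel).
#' @param noise A \code{\link{noise_model}}.
#' @param z Axial position recorded in the result (default 0).
#' @return A \code{fisher_result} (see \code{\link{fisher_matrix}}).
#' @export
fisher_from_gradients <- function(psf, grads, noise, z = 0) {
  stopifnot(length(grads) == 3)
  mu <- noise$photons * psf + noise$background
  # pixels with zero expected counts carry no information (their
  # gradients vanish with the PSF); exclude them from the quotient
  ok <- mu > 0
  q <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    q[i, j] <- q[j, i] <-
      sum((noise$photons * grads[[i]][ok]) *
            (noise$photons * grads[[j]][ok]) / mu[ok])
  }
  structure(list(q = q, z = z,
                 singular = all(abs(q) < .Machine$double.eps)),
            class = "fisher_result")
}

#' Brute-force Fisher matrix by central finite differences
#'
#' Independent reference implementation: PSF derivatives are estimated by
#' central differences of \code{\link{psf_at}} at perturbed emitter
#' positions and assembled into the Fisher sum directly. Used to validate
#' the analytic-gradient path; shares only the forward PSF model with it.
#'
#' @inheritParams fisher_matrix
#' @param step_xy,step_z Finite-difference steps in micrometres
#'   (defaults 0.01 um lateral, 0.05 um axial).
#' @return A \code{fisher_result} as in \code{\link{fisher_matrix}}.
#' @export
fisher_matrix_fd <- function(mask, config, theta = emitter_state(),
                             noise = noise_model(), crop = NULL,
                             step_xy = 0.01, step_z = 0.05) {
  check_mask_config(mask, config)
  crop <- crop %||% config$fov_n
  pert <- function(dx, dy, dz)
    psf_at(mask, config,
           emitter_state(theta$x0 + dx, theta$y0 + dy, theta$z0 + dz),
           crop = crop)
  d <- list(
    (pert(step_xy, 0, 0) - pert(-step_xy, 0, 0)) / (2 * step_xy),
    (pert(0, step_xy, 0) - pert(0, -step_xy, 0)) / (2 * step_xy),
    (pert(0, 0, step_z) - pert(0, 0, -step_z)) / (2 * step_z))
  mu <- noise$photons * psf_at(mask, config, theta, crop = crop) +
    noise$background
  ok <- mu > 0
  q <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3)
    q[i, j] <- q[j, i] <-
      sum((noise$photons * d[[i]][ok]) * (noise$photons * d[[j]][ok]) / mu[ok])
  structure(list(q = q, z = theta$z0,
                 singular = all(abs(q) < .Machine$double.eps)),
            class = "fisher_result")
}

#' Cramer-Rao lower bound from a Fisher matrix
#'
#' The CRLB variance for each position parameter is the corresponding
#' diagonal entry of the inverse Fisher matrix. Near-singular information
#' matrices are handled by an eigendecomposition: directions whose
#' eigenvalue falls below \code{max(eigenvalue) / cond_threshold} are
#' treated as unobservable and the affected components are reported at
#' the \code{cap} value and flagged. Finite components larger than
#' \code{cap} are likewise clipped to it (a bound can never usefully
#' exceed the prior range it is compared against).
#'
#' @param fisher A \code{fisher_result} from \code{\link{fisher_matrix}}.
#' @param cap Variance cap in um^2 (default \code{Inf}: no clipping,
#'   unobservable components come back \code{Inf}).
#' @param cond_threshold Condition-number threshold for treating an
#'   eigendirection as null (default 1e12).
#' @return Numeric 3-vector of variances (um^2) for (x0, y0, z0), with
#'   attributes \code{saturated} (logical 3-vector) and \code{precision}
#'   (sqrt of the variances, um).
#' @examples
#' f <- structure(list(q = diag(c(4, 4, 1)), z = 0, singular = FALSE),
#'                class = "fisher_result")
#' crlb(f)  # 0.25 0.25 1.00
#' @export
crlb <- function(fisher, cap = Inf, cond_threshold = 1e12) {
  q <- fisher$q
  e <- eigen(q, symmetric = TRUE)
  lam <- e$values
  good <- lam > max(lam, 0) / cond_threshold & lam > 0
  v <- rep(Inf, 3)
  sat <- rep(TRUE, 3)
  if (any(good)) {
    Vg <- e$vectors[, good, drop = FALSE]
    inv_diag <- rowSums(sweep(Vg^2, 2, lam[good], "/"))
    # a parameter is unobservable if it has weight in the null space
    null_w <- 1 - rowSums(Vg^2)
    sat <- null_w > 1e-8
    v[!sat] <- inv_diag[!sat]
  }
  over <- is.finite(cap) & v > cap
  sat <- sat | over
  v[v > cap] <- cap
  structure(v, saturated = sat, precision = sqrt(v))
}

#' Axial-range design cost: summed CRLB over the working range
#'
#' The design figure of merit for a 3D-localization mask: the CRLB for
#' (x0, y0, z0), evaluated on-axis, is sampled at \code{n_samples} equal
#' intervals across the axial range and summed over axial positions and
#' parameters. Samples are placed at interval midpoints, which also
#' avoids the exactly-symmetric focus point where the clear aperture's
#' axial information vanishes. Unobservable or out-of-bound components
#' contribute the cap \code{(zmax - zmin)^2}, interpreted as "no better
#' than already knowing the prior axial range".
#'
#' @param mask A \code{\link{phase_mask}}.
#' @param config An \code{\link{optical_config}}.
#' @param z_range Length-2 numeric \code{c(zmin, zmax)} in micrometres.
#' @param n_samples Number of axial samples (default 100).
#' @param noise A \code{\link{noise_model}}.
#' @param crop Optional centred crop side for the Fisher sums.
#' @return An object of class \code{crlb_profile}: \code{z_grid},
#'   \code{crlb} (n x 3 matrix of variances, um^2), \code{saturated}
#'   (n x 3 logical), \code{cost} (scalar, um^2), \code{cap}.
#' @export
design_cost <- function(mask, config, z_range, n_samples = 100,
                        noise = noise_model(), crop = NULL) {
  check_mask_config(mask, config)
  stopifnot(length(z_range) == 2, z_range[1] < z_range[2], n_samples >= 2)
  ctx <- pupil_ctx(config)
  crop <- crop %||% config$fov_n
  z_grid <- design_z_grid(z_range, n_samples)
  cap <- diff(z_range)^2
  cr <- matrix(NA_real_, n_samples, 3,
               dimnames = list(NULL, c("x", "y", "z")))
  sat <- matrix(NA, n_samples, 3)
  for (k in seq_len(n_samples)) {
    f <- fisher_matrix_ctx(ctx, mask$phase, emitter_state(z0 = z_grid[k]),
                           noise, crop = crop)
    v <- crlb(f, cap = cap)
    cr[k, ] <- as.numeric(v)
    sat[k, ] <- attr(v, "saturated")
  }
  structure(list(z_grid = z_grid, crlb = cr, saturated = sat,
                 cost = sum(cr), cap = cap, noise = noise),
            class = "crlb_profile")
}

# midpoints of n equal intervals over the range
design_z_grid <- function(z_range, n_samples) {
  step <- diff(z_range) / n_samples
  z_range[1] + (seq_len(n_samples) - 0.5) * step
}

#' @export
print.crlb_profile <- function(x, ...) {
  cat(sprintf("<crlb_profile> %d z-samples in [%g, %g] um; cost %.4g um^2",
              length(x$z_grid), min(x$z_grid), max(x$z_grid), x$cost))
  n_sat <- sum(x$saturated)
  if (n_sat > 0) cat(sprintf(" (%d capped components)", n_sat))
  cat("\n")
  invisible(x)
}

#' Export a CRLB profile as a data frame / CSV
#'
#' @param x A \code{crlb_profile}.
#' @param path Optional CSV path; when given the table is written there.
#' @return Data frame with columns z, crlb_x/y/z (um^2), and saturation
#'   flags.
#' @export
crlb_profile_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "crlb_profile"))
  df <- data.frame(z = x$z_grid,
                   crlb_x = x$crlb[, 1], crlb_y = x$crlb[, 2],
                   crlb_z = x$crlb[, 3],
                   sat_x = x$saturated[, 1], sat_y = x$saturated[, 2],
                   sat_z = x$saturated[, 3])
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
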