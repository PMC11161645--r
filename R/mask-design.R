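#' Settings for gradient-based phase-mask optimization
#'
#' Both designers (\code{\link{optimize_tetrapod}} and
#' \code{\link{optimize_edof}}) run plain gradient descent directly on
#' the per-pixel phase values of the pupil grid -- no Zernike-subspace
#' constraint -- with analytic gradients propagated through the
#' squared-modulus Fourier chain and a backtracking step control that
#' never accepts a cost increase.
#'
#' @param iterations Number of descent iterations (>= 0).
#' @param step_size Initial step scale: the first update changes the
#'   phase by at most this many radians (adapted thereafter).
#' @param seed RNG seed; all randomness (the small random
#'   symmetry-breaking initialization) flows through it.
#' @param z_range Axial design span \code{c(zmin, zmax)} in micrometres.
#' @param n_z Number of axial samples across the range (midpoints of
#'   equal intervals).
#' @param init Initialization: \code{"random-small"} (default; seeded
#'   zero-mean phases of 0.5 rad s.d., needed to break the focal
#'   symmetry), \code{"zeros"}, or a \code{\link{phase_mask}}.
#' @param record_every Record the cost every this many iterations.
#' @return An object of class \code{optimize_settings}.
#' @export
optimize_settings <- function(iterations = 300, step_size = 0.1, seed = 1,
                              z_range = c(-20, 20), n_z = 20,
                              init = "random-small", record_every = 10) {
  stopifnot(iterations >= 0, step_size > 0, n_z >= 2,
            length(z_range) == 2, z_range[1] < z_range[2],
            record_every >= 1)
  structure(list(iterations = as.integer(iterations), step_size = step_size,
                 seed = as.integer(seed), z_range = as.numeric(z_range),
                 n_z = as.integer(n_z), init = init,
                 record_every = as.integer(record_every)),
            class = "optimize_settings")
}

# initial phase grid (n x n) per the settings; seeded and aperture-masked
init_phase <- function(ctx, settings) {
  n <- ctx$n
  if (inherits(settings$init, "phase_mask")) {
    check_mask_config(settings$init, ctx$config)
    return(settings$init$phase)
  }
  switch(settings$init,
    "zeros" = matrix(0, n, n),
    "random-small" = {
      set.seed(settings$seed)
      matrix(stats::rnorm(n * n, sd = 0.5), n, n) * ctx$grid$aperture
    },
    stop("unknown init: ", settings$init))
}

# ---- shared gradient-descent engine -----------------------------------------

# cost_grad(M) must return list(cost = scalar, grad = n x n matrix).
# Monotone: a step is only accepted if it does not increase the cost;
# otherwise the step is halved (up to max_halvings, then the run stops).
gd_optimize <- function(M0, cost_grad, iterations, step_size, record_every,
                        aperture, max_halvings = 20) {
  cg <- cost_grad(M0)
  if (!is.finite(cg$cost)) stop("initial cost is not finite")
  history <- data.frame(iteration = 0L, cost = cg$cost)
  M <- M0
  it_done <- 0L
  if (iterations > 0) {
    gmax <- max(abs(cg$grad))
    step <- if (gmax > 0) step_size / gmax else 0
    for (it in seq_len(iterations)) {
      if (step == 0) break
      accepted <- FALSE
      for (h in seq_len(max_halvings)) {
        cand <- (M - step * cg$grad) * aperture
        cg_new <- cost_grad(cand)
        if (is.finite(cg_new$cost) && cg_new$cost <= cg$cost) {
          M <- cand; cg <- cg_new; step <- step * 1.2; accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) break
      it_done <- it
      if (it %% record_every == 0)
        history <- rbind(history, data.frame(iteration = it, cost = cg$cost))
    }
    if (utils::tail(history$iteration, 1) != it_done)
      history <- rbind(history,
                       data.frame(iteration = it_done, cost = cg$cost))
  }
  list(phase = M, history = history, final_cost = cg$cost)
}

# ---- Tetrapod: per-pixel CRLB optimization ----------------------------------

# cost and analytic mask-gradient of the summed-CRLB design cost at one z.
# Backpropagation through Q = sum (N dP_a)(N dP_b)/(N P + B):
#   dcost/dP   = -N * sum_ab H_ab g_a g_b / mu^2
#   dcost/dP_a = 2N * sum_b H_ab g_b / mu
# with H = -(Qinv Dsel Qinv), Dsel selecting un-capped components, and
# then through the Fourier chain via the adjoint DFT.
tetrapod_cost_grad_z <- function(ctx, M, z, noise, cap, cond_threshold = 1e12) {
  g <- psf_gradient_ctx(ctx, M, emitter_state(z0 = z), keep_fields = TRUE)
  N_ph <- noise$photons
  mu <- N_ph * g$psf + noise$background
  ga <- list(N_ph * g$dx, N_ph * g$dy, N_ph * g$dz)
  q <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3)
    q[i, j] <- q[j, i] <- sum(ga[[i]] * ga[[j]] / mu)
  e <- eigen(q, symmetric = TRUE)
  lam <- e$values
  good <- lam > max(lam, 0) / cond_threshold & lam > 0
  if (!any(good)) {
    return(list(cost = 3 * cap, grad = matrix(0, ctx$n, ctx$n)))
  }
  Vg <- e$vectors[, good, drop = FALSE]
  Qi <- Vg %*% (t(Vg) / lam[good])
  inv_diag <- diag(Qi)
  null_w <- 1 - rowSums(Vg^2)
  sat <- null_w > 1e-8 | inv_diag > cap
  vals <- ifelse(sat, cap, inv_diag)
  sel <- diag(as.numeric(!sat))
  H <- -(Qi %*% sel %*% Qi)
  # image-plane adjoints
  G <- mu * 0
  for (a in 1:3) for (b in 1:3)
    if (H[a, b] != 0) G <- G + H[a, b] * ga[[a]] * ga[[b]]
  G <- -N_ph * G / mu^2
  Ga <- lapply(1:3, function(a) {
    acc <- mu * 0
    for (b in 1:3) if (H[a, b] != 0) acc <- acc + H[a, b] * ga[[b]]
    2 * N_ph * acc / mu
  })
  grad <- mask_grad_adjoint(ctx, g, G, Ga)
  list(cost = sum(vals), grad = grad)
}

# adjoint of the PSF(-gradient) chain onto the pupil phase. G is the
# sensitivity to the PSF plane; Ga (optional) the sensitivities to the
# three position-derivative planes.
mask_grad_adjoint <- function(ctx, g, G, Ga = NULL) {
  emb <- ctx$emb
  W <- G * Conj(g$U)
  if (!is.null(Ga)) {
    W <- W + Ga[[1]] * Conj(g$V$x) + Ga[[2]] * Conj(g$V$y) +
      Ga[[3]] * Conj(g$V$z)
  }
  A <- ftc(W)[emb, emb]
  grad <- 2 / ctx$norm * Re(1i * g$E * A)
  if (!is.null(Ga)) {
    ramps <- list(ctx$cx, ctx$cy, ctx$psi)
    for (a in 1:3) {
      B <- ftc(Ga[[a]] * Conj(g$U))[emb, emb]
      grad <- grad - 2 / ctx$norm * ramps[[a]] * Re(g$E * B)
    }
  }
  grad * ctx$grid$aperture
}

#' Design a Tetrapod-type mask by per-pixel CRLB minimization
#'
#' Minimizes the axial-range design cost of \code{\link{design_cost}} --
#' the CRLB for (x0, y0, z0) summed over axial samples spanning the
#' design range -- by gradient descent on the per-pixel pupil phase.
#' Gradients are exact (analytic backpropagation through the Fisher
#' matrix inverse and the Fourier optics chain). The optimization is
#' deterministic given \code{settings$seed}; the recorded cost history is
#' non-increasing by construction.
#'
#' @param config An \code{\link{optical_config}}.
#' @param settings An \code{\link{optimize_settings}} (axial range,
#'   iterations, seed, ...).
#' @param noise A \code{\link{noise_model}} giving the signal/background
#'   photon levels the design is optimized for.
#' @return List with \code{mask} (the optimized \code{\link{phase_mask}}),
#'   \code{history} (data frame iteration/cost), \code{initial_cost} and
#'   \code{final_cost} (um^2).
#' @export
optimize_tetrapod <- function(config, settings = optimize_settings(),
                              noise = noise_model()) {
  stopifnot(inherits(config, "optical_config"),
            inherits(settings, "optimize_settings"))
  ctx <- pupil_ctx(config)
  z_grid <- design_z_grid(settings$z_range, settings$n_z)
  cap <- diff(settings$z_range)^2
  cost_grad <- function(M) {
    tot <- 0; grad <- matrix(0, ctx$n, ctx$n)
    for (z in z_grid) {
      r <- tetrapod_cost_grad_z(ctx, M, z, noise, cap)
      tot <- tot + r$cost; grad <- grad + r$grad
    }
    list(cost = tot, grad = grad)
  }
  M0 <- init_phase(ctx, settings)
  res <- gd_optimize(M0, cost_grad, settings$iterations, settings$step_size,
                     settings$record_every, ctx$grid$aperture)
  list(mask = phase_mask(res$phase, label = "tetrapod"),
       history = res$history,
       initial_cost = res$history$cost[1], final_cost = res$final_cost)
}

# ---- EDOF: Gaussian-target phase retrieval ----------------------------------

#' Design an EDOF mask by Gaussian-target phase retrieval
#'
#' Retrieves the pupil phase whose PSF best approximates a fixed narrow
#' 2D Gaussian profile at equal axial intervals spanning the design
#' range: the cost is the mean-square difference between the PSF and
#' the (non-changing) Gaussian profile, summed over the axial samples.
#' The profile is a shape target: its amplitude is matched to each
#' plane by least squares (\code{a = <PSF, G> / <G, G>}), so the design
#' is not forced to push every photon into the core -- a physical
#' impossibility over an extended range -- but to keep a tight,
#' Gaussian-shaped core at every depth, tolerating a weak halo. The
#' result is an extended-depth-of-field PSF. The algorithm is robust to
#' the exact target width; the default is the diffraction-limited width
#' \code{0.21 * wavelength / na}.
#'
#' @inheritParams optimize_tetrapod
#' @param target_sigma Target Gaussian standard deviation in micrometres
#'   (default: diffraction-limited).
#' @return As \code{\link{optimize_tetrapod}} (cost in squared intensity
#'   fraction units).
#' @export
optimize_edof <- function(config, settings = optimize_settings(z_range = c(-30, 30)),
                          target_sigma = NULL) {
  stopifnot(inherits(config, "optical_config"),
            inherits(settings, "optimize_settings"))
  ctx <- pupil_ctx(config)
  if (is.null(target_sigma)) target_sigma <- 0.21 * config$wavelength / config$na
  stopifnot(target_sigma > 0)
  z_grid <- design_z_grid(settings$z_range, settings$n_z)
  target <- gaussian_image(ctx$N, target_sigma / ctx$dx)
  tt <- sum(target^2)
  cost_grad <- function(M) {
    tot <- 0; grad <- matrix(0, ctx$n, ctx$n)
    for (z in z_grid) {
      g <- psf_gradient_edof(ctx, M, z)
      # per-plane least-squares amplitude of the profile; the gradient
      # 2*(P - a*T) is exact because d(cost)/d(a) = 0 at the optimum
      a <- sum(g$psf * target) / tt
      d <- g$psf - a * target
      tot <- tot + sum(d^2)
      grad <- grad + mask_grad_adjoint(ctx, g, 2 * d)
    }
    list(cost = tot, grad = grad)
  }
  M0 <- init_phase(ctx, settings)
  res <- gd_optimize(M0, cost_grad, settings$iterations, settings$step_size,
                     settings$record_every, ctx$grid$aperture)
  list(mask = phase_mask(res$phase, label = "edof-retrieved"),
       history = res$history,
       initial_cost = res$history$cost[1], final_cost = res$final_cost)
}

# forward pass only (PSF + fields), no position derivatives
psf_gradient_edof <- function(ctx, M, z) {
  E <- pupil_field(ctx, M, emitter_state(z0 = z))
  U <- ftc(embed_pupil(ctx, E))
  list(psf = Re(U * Conj(U)) / ctx$norm, E = E, U = U)
}

# centred unit-sum 2D Gaussian on an N x N grid (sigma in pixels)
gaussian_image <- function(N, sigma_px) {
  p <- seq.int(-N / 2, N / 2 - 1)
  g1 <- exp(-p^2 / (2 * sigma_px^2))
  g <- outer(g1, g1)
  g / sum(g)
}

# ---- incoherent multizone EDOF element --------------------------------------

#' Equal-DOF multizone element design
#'
#' Partitions the objective aperture into \code{n_layers + 1} annular
#' zones separated by stacked glass layers. Each layer adds an optical
#' path difference far beyond the fluorescence coherence length, so the
#' zones add incoherently. Zone boundaries are chosen so every zone
#' produces the same depth of field: since defocus phase grows as rho^2
#' to leading order, equal-DOF means equal rho^2 increments, i.e. radii
#' \code{r_k = (D/2) * sqrt(k / (n_layers + 1))}.
#'
#' @param aperture_diameter Objective aperture diameter in millimetres.
#' @param n_layers Number of glass layers (>= 0).
#' @param layer_thickness Thickness of each layer in millimetres
#'   (default 0.17, a standard coverslip).
#' @param delta_n Refractive-index difference between the layer material
#'   and air (default 0.5).
#' @return An object of class \code{multizone_design} with fields
#'   \code{diameters} (mm, raw), \code{diameters_rounded} (0.1 mm),
#'   \code{n_zones}, \code{path_difference} (um per layer), and the
#'   inputs.
#' @examples
#' d <- multizone_diameters(12, 3)
#' d$diameters_rounded  # 6.0 8.5 10.4
#' @export
multizone_diameters <- function(aperture_diameter, n_layers,
                                layer_thickness = 0.17, delta_n = 0.5) {
  stopifnot(aperture_diameter > 0, n_layers >= 0)
  n_layers <- as.integer(n_layers)
  k <- seq_len(n_layers)
  diameters <- aperture_diameter * sqrt(k / (n_layers + 1))
  structure(list(aperture_diameter = aperture_diameter,
                 n_layers = n_layers,
                 n_zones = n_layers + 1L,
                 diameters = diameters,
                 diameters_rounded = round(diameters, 1),
                 layer_thickness = layer_thickness,
                 delta_n = delta_n,
                 path_difference = path_difference(layer_thickness, delta_n)),
            class = "multizone_design")
}

#' @export
print.multizone_design <- function(x, ...) {
  cat(sprintf("<multizone_design> %d layers -> %d incoherent zones in a %g mm aperture\n",
              x$n_layers, x$n_zones, x$aperture_diameter))
  if (x$n_layers > 0)
    cat("  layer diameters (mm): ",
        paste(format(x$diameters_rounded, nsmall = 1), collapse = ", "), "\n")
  cat(sprintf("  path difference per layer: %g um\n", x$path_difference))
  invisible(x)
}

#' Optical path difference introduced by one glass layer
#'
#' @param layer_thickness Layer thickness in millimetres.
#' @param delta_n Refractive-index difference to air.
#' @return Path difference in micrometres
#'   (\code{thickness * delta_n}, unit-converted).
#' @examples
#' path_difference(0.17, 0.5)  # 85 um
#' @export
path_difference <- function(layer_thickness, delta_n) {
  stopifnot(layer_thickness >= 0, delta_n >= 0)
  layer_thickness * delta_n * 1000
}

#' Fluorescence coherence length
#'
#' The path difference beyond which a source of centre wavelength
#' \code{lambda} and bandwidth \code{dlambda} stops interfering with
#' itself: \code{lambda^2 / dlambda}. Fluorescent emission bands of a few
#' tens of nanometres give coherence lengths of order 10 um, far shorter
#' than the ~85 um per-layer path difference of the multizone element.
#'
#' @param center_wavelength Centre wavelength in micrometres.
#' @param bandwidth Emission bandwidth in micrometres (> 0).
#' @return Coherence length in micrometres.
#' @export
coherence_length <- function(center_wavelength, bandwidth) {
  stopifnot(bandwidth > 0)
  center_wavelength^2 / bandwidth
}

#' PSF of the incoherent multizone element
#'
#' Each annular zone diffracts independently (the inter-layer path
#' differences exceed the coherence length), so the PSF at every axial
#' position is the incoherent, area-fraction-weighted sum of the PSFs of
#' the zone-restricted apertures. With the equal-DOF partition all area
#' fractions are equal.
#'
#' @param design A \code{\link{multizone_diameters}} result.
#' @param config An \code{\link{optical_config}}; its
#'   \code{pupil_diameter} must be at least the design aperture.
#' @param z_grid Strictly increasing axial positions (um).
#' @param crop Optional centred crop side (pixels), default
#'   \code{config$fov_n}.
#' @return A \code{psf_stack} (unit-normalized per plane).
#' @export
multizone_psf <- function(design, config, z_grid, crop = NULL) {
  stopifnot(inherits(design, "multizone_design"),
            inherits(config, "optical_config"))
  if (design$n_layers > 0 &&
      max(design$diameters) >= design$aperture_diameter)
    stop("zone diameters must be smaller than the aperture")
  if (design$aperture_diameter > config$pupil_diameter)
    stop("design aperture exceeds the configured pupil diameter")
  if (length(z_grid) == 0) stop("z_grid must be nonempty")
  if (is.unsorted(z_grid, strictly = TRUE))
    stop("z_grid must be strictly increasing")
  ctx <- pupil_ctx(config)
  crop <- crop %||% config$fov_n
  # zone boundaries in normalized pupil radius (rim of the design aperture
  # mapped to rho = design/config aperture ratio; usually 1)
  rim <- design$aperture_diameter / config$pupil_diameter
  bounds <- c(-1, design$diameters / config$pupil_diameter, rim)
  rho <- ctx$grid$rho
  zones <- lapply(seq_len(design$n_zones), function(j)
    ctx$grid$aperture & rho > bounds[j] & rho <= bounds[j + 1])
  areas <- vapply(zones, sum, numeric(1))
  w <- areas / sum(areas)
  side <- if (is.null(crop)) ctx$N else crop
  values <- array(0, dim = c(length(z_grid), side, side))
  for (k in seq_along(z_grid)) {
    ph <- z_grid[k] * ctx$psi
    acc <- matrix(0, ctx$N, ctx$N)
    for (j in seq_len(design$n_zones)) {
      if (areas[j] == 0) next
      E <- ifelse(zones[[j]], exp(1i * ph), 0 + 0i)
      U <- ftc(embed_pupil(ctx, E))
      acc <- acc + w[j] * Re(U * Conj(U)) / (ctx$N^2 * areas[j])
    }
    values[k, , ] <- if (is.null(crop)) acc else crop_center(acc, crop)
  }
  structure(list(values = values, z_grid = as.numeric(z_grid),
                 pixel_pitch = ctx$dx),
            class = "psf_stack")
}

# ---- fabrication conversion -------------------------------------------------

#' Convert a phase mask to an etch-depth map
#'
#' A phase delay of \code{phi} radians at the design wavelength is
#' produced by etching to depth
#' \code{phi * wavelength / (2 * pi * (material_index - 1))} in a
#' substrate of the given refractive index (quartz: ~1.46). Phases are
#' wrapped to [0, 2*pi) first, so depths span one full wave:
#' [0, wavelength / (material_index - 1)).
#'
#' @param mask A \code{\link{phase_mask}}.
#' @param wavelength Design (emission) wavelength in micrometres.
#' @param material_index Substrate refractive index (> 1).
#' @return An object of class \code{depth_map}: \code{depth} (um, same
#'   grid as the mask), \code{wavelength}, \code{material_index}.
#' @export
phase_to_depth <- function(mask, wavelength, material_index = 1.46) {
  stopifnot(inherits(mask, "phase_mask"), wavelength > 0)
  if (material_index <= 1)
    stop("material_index must exceed 1 (air) for an etched element")
  depth <- wrap_phase(mask$phase) * wavelength /
    (2 * pi * (material_index - 1))
  structure(list(depth = depth, wavelength = wavelength,
                 material_index = material_index, label = mask$label),
            class = "depth_map")
}

#' Recover the wrapped phase mask from a depth map
#'
#' Inverse of \code{\link{phase_to_depth}}.
#'
#' @param dm A \code{depth_map}.
#' @return A \code{\link{phase_mask}} with phases in [0, 2*pi).
#' @export
depth_to_phase <- function(dm) {
  stopifnot(inherits(dm, "depth_map"))
  phase_mask(dm$depth * 2 * pi * (dm$material_index - 1) / dm$wavelength,
             label = dm$label)
}
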