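---
title: "Engineering point-spread functions: model, designers, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engineering point-spread functions: model, designers, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(psfengine)
```

This vignette is the package's account of the science it implements: the
optical forward model and its assumptions, the statistical machinery that
turns a phase mask into a localization bound, the three mask designers,
what the synthetic-data generators do and do not emulate, and the
numerical choices made where the design was genuinely open.

## The forward model

A fluorescent point source imaged by a low-NA microscope objective is
modelled with scalar Fourier optics. The back focal plane (BFP) carries
the field

$$E(\rho) = A(\rho)\,\exp\!\big[i\,(M(\rho) + z_0\,\psi(\rho) +
x_0 c_x + y_0 c_y)\big],$$

where $A$ is a uniform circular aperture ($\rho \le 1$), $M$ the design
phase mask, $\psi(\rho) = \tfrac{2\pi}{\lambda}\sqrt{n^2 -
\mathrm{NA}^2\rho^2}$ the exact (non-paraxial) defocus rate per
micrometre of axial position, and $c_x, c_y$ linear ramps implementing
lateral position. The camera-plane PSF is $|\mathcal{F}\{E\}|^2$,
unit-normalized over the full transform plane (Parseval makes the
normalizer a constant, which every test of energy conservation relies
on).

Assumptions worth stating explicitly:

* **Scalar, uniform-amplitude pupil.** At NA 0.3 polarization effects
  are small; no apodization profile is modelled.
* **No index-mismatch or field-dependent aberrations.** The axial
  coordinate is position relative to the nominal focal plane of an
  aberration-free system.
* **Pure shot noise.** Pixels are independent Poisson counts with mean
  `photons * PSF + background`; the per-pixel background is a single
  scalar. No read noise, gain, or offset.

Sampling is set by the FFT: a pupil grid of `grid_n` pixels padded by
`pad_factor` gives a sample-plane pixel of
$\lambda/(2\,\mathrm{NA}\cdot\mathrm{pad})$ — 0.437 µm at the defaults
(NA 0.3, 524 nm, pad 2), independent of `grid_n`. A configuration may
carry a camera-derived pitch as metadata; `check_sampling()` warns when
it disagrees with the FFT grid by more than 5 %, because simulated and
experimental pixel grids are then not directly comparable. Defaults
throughout: `grid_n = 128` for plain simulation, 64 for the optimization
loops; both keep the defocus fringes at the pupil rim well sampled over
the ±30 µm ranges used here.

## Fisher information and the CRLB

For Poisson data the log-likelihood of an image $I$ given emitter
position $\Theta = (x_0, y_0, z_0)$ is
$\sum_{x,y} I\log\mu - \mu$ with $\mu = N\,\mathrm{PSF} + B$; the term
depending only on the data is dropped (it cancels in every derivative).
The Fisher information is

$$Q_{ij} = \sum_{x,y} \frac{(N\,\partial_i \mathrm{PSF})\,
(N\,\partial_j \mathrm{PSF})}{N\,\mathrm{PSF} + B},$$

and the CRLB for each coordinate is the corresponding diagonal entry of
$Q^{-1}$. The PSF derivatives are exact: the lateral ones differentiate
the shift ramp, the axial one the defocus rate, each a single extra FFT.
`fisher_matrix_fd()` is an independent brute-force check that estimates
the same derivatives by central differences (10 nm lateral, 50 nm
axial steps); the two agree to well under 1 %.

**Near-singular information.** The clear aperture at focus carries
essentially no axial information ($\partial_z \mathrm{PSF} \to 0$), so
$Q$ becomes ill-conditioned. `crlb()` eigendecomposes $Q$; directions
whose eigenvalue falls below $\lambda_{max}/10^{12}$ are declared
unobservable and reported at a cap, and finite variances above the cap
are clipped to it. In `design_cost()` the cap is the squared axial span,
read as "no better than already knowing the prior range". On the
discrete FFT grid the focal singularity is softened (the even grid has
no partner for its first row/column, leaving $Q_{zz}$ at roughly
$10^{-7}$ of $Q_{xx}$ instead of exactly zero), so near-focus axial
variances are enormous rather than formally infinite; the cap treats
both cases identically.

## The axial-range design cost and the Tetrapod designer

The design figure of merit sums the three CRLB components over axial
samples spanning the working range, evaluated on-axis. Samples sit at
the midpoints of 100 equal intervals: midpoints represent each interval
without privileging its edges and avoid placing a sample exactly at the
symmetric focus. The signal level the design assumes is configurable and
defaults to 5000 signal photons with 10 background photons per pixel —
typical single-molecule-scale counts.

`optimize_tetrapod()` descends this cost directly over the per-pixel
pupil phase (no Zernike subspace), using exact gradients obtained by
backpropagating through the matrix inverse
($\partial\,\mathrm{tr}\,Q^{-1} = -Q^{-1}\,\partial Q\,Q^{-1}$) and the
$|\mathcal{F}\{\cdot\}|^2$ chain via adjoint FFTs — about eight FFTs per
axial sample per iteration. The step size is controlled by backtracking:
a step is only accepted if the cost does not increase, so the recorded
history is non-increasing by construction; accepted steps grow the step
length by 1.2×, rejected ones halve it. Initialization is a seeded
zero-mean random phase (s.d. 0.5 rad): the zero mask is a symmetric
stationary point, and white-noise phases give finite axial information
everywhere in the range so gradients flow from the first iteration. The
whole optimization is bitwise deterministic given the seed.

At desk scale (64-pixel pupil, ±20 µm range, 20 axial samples for the
optimization loop, 300 iterations, about two minutes on one CPU) the
optimized mask reaches roughly one third of the clear-aperture cost when
both are evaluated with the standard 100-interval cost, and holds the
axial precision bound near 0.1 µm across the whole range where the clear
aperture's near-focus bound explodes. The optimization grid (20 samples)
is deliberately coarser than the evaluation grid (100): the cost surface
is smooth in z, and the 5× cheaper loop converges to the same masks in
our experience.

## EDOF by Gaussian-target phase retrieval

The extended-depth-of-field designer asks for a different property: a
PSF that stays a tight, Gaussian-shaped spot at every depth across a
60 µm range. Its cost is the mean-square difference between the PSF and
a fixed narrow Gaussian profile at equal axial intervals spanning the
range, with one important reading: the Gaussian is a **shape** target.
Its amplitude is matched to each plane by least squares
($a_z = \langle \mathrm{PSF}, G\rangle / \langle G, G\rangle$, making
the gradient $2(\mathrm{PSF} - a_z G)$ exact). Forcing the profile's
absolute energy instead is physically impossible over an extended range
— a finite photon budget cannot sit entirely in a diffraction-limited
core at 20 depths at once — and we found that every optimizer given the
hard-energy target (gradient descent, adaptive-step variants,
alternating amplitude projections, even starts from a cubic wavefront
that already has excellent depth of field) converges to solutions that
concentrate light at a few planes and *reduce* the usable depth of
field. With the shape reading, plain gradient descent from the seeded
random start robustly yields flat width curves: fitted widths around
0.42 µm varying by less than 20 % over roughly ±20 µm at NA 0.3, where
the clear aperture holds its width over about ±4 µm.

The target width defaults to the diffraction-limited
$0.21\,\lambda/\mathrm{NA}$; the outcome is insensitive to the exact
choice (we verified factors of 1.5–3× on the width change the attained
depth-of-field factor only marginally), consistent with the robustness
one expects from a shape-matching cost.

## The incoherent multizone element

The second EDOF route is hardware rather than optimization: stacked
glass layers partition the BFP into concentric annular zones. Each layer
adds an optical path difference of `thickness × Δn` — 85 µm for a
0.17 mm coverslip at Δn ≈ 0.5 — which dwarfs the fluorescence coherence
length $\lambda^2/\Delta\lambda$ (about 7 µm for a 40 nm-wide green
emission band), so the zones cannot interfere and the PSF is the
area-weighted incoherent sum of the zone PSFs. Because defocus phase
grows as $\rho^2$ to leading order, equal depth of field per zone means
equal $\rho^2$ increments: radii $r_k = (D/2)\sqrt{k/(n+1)}$. For a
12 mm aperture and three layers this gives layer diameters of
[6.0, 8.5, 10.4] mm, each zone then covering the same defocus-phase
spread to within a few percent (the non-paraxial correction at NA 0.3 is
below the rasterization error). `phase_to_depth()` converts any designed
phase profile to an etch-depth map for photolithography,
$d = \phi\,\lambda / (2\pi(n_{quartz}-1))$, wrapping to one full wave.

## Synthetic scenes and tracks

The generators exist so that every evaluation in the package runs
without external data, and their defaults are the conditions the
evaluations assume:

* `random_bead_scene()` — beads in gel: Poisson count at 22,000 beads
  per mm³, uniform positions, constant expected brightness per bead.
* `spheroid_shell_scene()` — nuclei placed uniformly on a spherical
  shell; a purely geometric stand-in for a labelled spheroid, intended
  for demos. No biological realism (size distributions, layering,
  scattering, depth-dependent signal loss) is claimed.
* `simulate_brownian_tracks()` — per-axis Gaussian increments of
  variance $2D\,\Delta t$ plus independent per-frame localization noise;
  the 2.4 s default frame period is a 0.4 s exposure plus 2.0 s delay.
  No motion blur within the exposure, no track linking errors, no
  missed detections.

Rendering places emitters with exact sub-pixel positions through the
pupil ramp (the same mechanism the Fisher derivatives differentiate),
adds the scalar background, and Poisson-samples when asked; all
randomness flows through explicit seeds. Consequently, passing tests
show the estimators are correct *under the forward model's own
assumptions*; they say nothing about camera artefacts, aberrations, or
sample-induced background structure in real data.

## Evaluation machinery: numerical choices

**Width fitting.** PSF widths are measured by least-squares isotropic
Gaussian fits (Nelder–Mead with restarts). Two robustness measures
matter in practice: multi-start (a moment-based start plus narrow
centred starts, because a tight core on a broad halo misleads moment
initialization), and a fit-quality gate — the fitted Gaussian must
explain at least 5 % of the patch variance, otherwise the plane is
flagged rather than reported. Outside an EDOF design range the PSF
fragments into speckle; without the gate, a "fit" latching onto one
speckle grain reports a meaningless tiny width that poisons any
downstream minimum. FWHM is reported as $2\sqrt{2\ln 2}\,\sigma$.

**Depth of field.** The DOF of a width curve is the contiguous axial
span around the width minimum where
$\sigma \le 1.5\,\sigma_{min}$; `dof_factor()` is the ratio of two such
spans on a shared z grid. The 1.5 threshold is a package default, chosen
as a tolerant but unambiguous "still compact" criterion; it is exposed
as a parameter because no universal convention exists.

**MLE localization.** `mle_localize()` maximizes the Poisson likelihood
with a derivative-free simplex, optionally multi-started over z
(symmetric PSFs have mirror-image likelihood modes). With the Tetrapod
mask at 5000 photons, the Monte Carlo standard deviation of the
estimates matches $\sqrt{\mathrm{CRLB}}$ within a few percent on all
three axes — the estimator attains the bound it was designed against,
which is simultaneously a check of the Fisher machinery and of the
simulator.

**Richardson–Lucy.** The standard multiplicative update with circular
FFT convolution and the kernel normalized to unit sum, which conserves
flux to fractional $10^{-6}$ per iteration and is exactly the identity
under a delta kernel. Zero iterations returns the input.

**MSD fitting.** The ensemble MSD per axis is fit with
$\mathrm{MSD}(\tau) = 2D\tau + 2s^2$ over lags 1–10. MSD values at
different lags are computed from the same displacements and are strongly
correlated, so a diagonal weighted fit wastes most of the information
about the intercept; with 20 or more tracks the fit is generalized least
squares with the between-lag covariance estimated by bootstrap over
tracks (internal fixed seed; the caller's RNG state is restored). At the
reference conditions (100 tracks × 100 frames, D = 0.05 µm²/s,
s = 0.1 µm, Δt = 2.4 s) D is recovered within a few percent; the
intercept-derived s is intrinsically noisier (its share of the lag-1 MSD
is only ~8 %), with a sampling s.d. around 10–15 % — recovery within
25 % is the realistic expectation, and a negative fitted intercept is
floored at zero and flagged.

## Problem sizes

The test suite and the acceptance script use 64-pixel pupils (128² FFTs)
for the optimization loops and Monte Carlo, and 128-pixel pupils for
pure forward-model oracles; design ranges are ±20 µm (Tetrapod) and
±30 µm (EDOF) with 20 axial samples in the optimization loop and the
standard 100-interval grid for cost evaluation. These sizes reproduce
all the qualitative behaviour of larger designs (the fabricated-mask
regime of hundreds of micrometres simply scales the range parameter) and
keep a full design-evaluate-verify cycle in a few CPU-minutes.

## Known limitations

* Scalar, aberration-free optics: no vectorial high-NA effects, no
  refractive-index mismatch with depth, no field dependence.
* The designers return a local optimum of a non-convex landscape;
  different seeds give different masks of closely similar cost (the
  design cost ratio varies in the third decimal across seeds, but the
  phase patterns differ).
* The detector model is pure Poisson; cameras with significant read
  noise need a different likelihood, which also changes the CRLB.
* `detect_and_localize()` is a deliberately simple spot finder for
  well-separated emitters; overlapping-PSF multi-emitter fitting is out
  of scope.
* Tracks come labelled from the simulator; linking detections across
  frames is not implemented.
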