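# psfengine

Point-spread-function (PSF) engineering for high-throughput fluorescence
microscopy, in R.

Placing a phase mask in the back focal plane of a microscope objective
reshapes the PSF, and with it what a single 2D snapshot can tell you
about a 3D sample. Two engineered PSFs dominate this space at low NA:

* the **Tetrapod-type PSF**, whose shape encodes the emitter's depth
  over a large axial range, enabling 3D localization and tracking from
  single frames;
* the **EDOF PSF** (extended depth of field), which stays a compact spot
  over an enlarged axial range, turning each frame into an optical
  z-projection.

`psfengine` implements the full design–evaluate loop for both, for
people who design masks, simulate imaging systems, or need a rigorous
localization-precision bound: scalar Fourier-optics PSF simulation, the
Poisson-noise Fisher information and Cramér–Rao lower bound (CRLB),
per-pixel CRLB-driven mask optimization, Gaussian-target EDOF phase
retrieval, the incoherent multizone (stacked-glass) EDOF element, etch
depth-map conversion for fabrication, synthetic bead/spheroid/tracking
scenes, maximum-likelihood localization, Richardson–Lucy deconvolution,
and MSD-based diffusion analysis.

## The model in brief

A point source at $\Theta = (x_0, y_0, z_0)$ produces the camera image

$$I(x,y) \sim \mathrm{Poiss}\big(N\cdot\mathrm{PSF}(x,y,M;\Theta) + B\big),
\qquad \mathrm{PSF} = \big|\mathcal{F}\{A\,e^{i(M + z_0\psi + \text{shift})}\}\big|^2,$$

with $M$ the pupil phase mask, $\psi$ the defocus rate, $N$ the signal
photons and $B$ a scalar background. The Fisher information

$$Q_{ij}(\Theta; M) = \sum_{x,y}
\frac{N^2\,\partial_i\mathrm{PSF}\cdot\partial_j\mathrm{PSF}}
{N\,\mathrm{PSF} + B}$$

bounds any unbiased estimator's variance by
$\mathrm{CRLB}_i = [Q^{-1}]_{ii}$. The Tetrapod designer minimizes
$\sum_z\sum_i \mathrm{CRLB}_i(z; M)$ over 100 axial samples spanning the
working range, by gradient descent directly on the per-pixel pupil
phase with exact adjoint-FFT gradients. See the `mask-design` vignette
for the model's assumptions and every numerical choice.

## Worked example

Design the incoherent multizone EDOF element and a desk-scale Tetrapod
mask, and compare the Tetrapod's localization bound to the clear
aperture (the second step runs the 300-iteration optimization, about two
minutes on one CPU):

```r
library(psfengine)

optical_config()            # 10x / NA 0.3 system, green emission
#> <optical_config>
#>   NA 0.3, lambda 0.524 um, mag 10x, pupil 12 mm, n(medium) 1
#>   pupil grid 128 px, pad 2x -> image pitch 0.4367 um/px

multizone_diameters(12, 3)  # equal-DOF glass-layer partition
#> <multizone_design> 3 layers -> 4 incoherent zones in a 12 mm aperture
#>   layer diameters (mm):   6.0,  8.5, 10.4
#>   path difference per layer: 85 um

coherence_length(0.524, 0.040)   # um; << 85 um, so the zones add incoherently
#> [1] 6.8644

cfg <- optical_config(grid_n = 64)
tp <- optimize_tetrapod(cfg,
  optimize_settings(iterations = 300, z_range = c(-20, 20), n_z = 20, seed = 1))
prof_tp <- design_cost(tp$mask, cfg, c(-20, 20))
prof_0  <- design_cost(zero_mask(cfg), cfg, c(-20, 20))
prof_tp$cost / prof_0$cost
#> [1] 0.343
sqrt(range(prof_tp$crlb[, 3]))
#> [1] 0.074 0.106
```

The optimized mask reaches about a third of the clear aperture's summed
CRLB over the ±20 µm range and bounds the axial localization error
between 74 and 106 nm everywhere in it, where the clear aperture's
axial bound diverges near focus.

Masks and PSF stacks are exchanged as 32-bit float TIFF with JSON
sidecars (`save_mask()`, `save_stack()`); a command-line wrapper with
`simulate-psf`, `optimize-mask`, `design-multizone`, `render-scene`,
`eval-dof`, `localize` and `msd` subcommands is installed under
`inst/cli/psfengine` (see `?cli`).

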