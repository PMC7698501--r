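---
title: "Dual-exposure motion-blur velocimetry: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-exposure motion-blur velocimetry: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowblur)
```

## The measurement principle

A particle moving at velocity $v$ along the flow axis while the sensor
integrates for time $t$ leaves an image that is its stationary shape
swept along the flow axis by the distance $v t$ — geometrically, the
Minkowski sum of the shape with a segment of length $v t$. After
binarization, a disk of diameter $d$ px therefore has flow-axis extent

$$L = d + \frac{v\,t}{p} \quad \text{[px]},$$

with $p$ the pixel size. A single such length confounds size and
motion. The dual-exposure trick acquires **two** images of the same
instant at different wavelengths with different irradiation times $t_1
> t_2$, both starting when the shutter opens (the short exposure is a
temporal prefix of the long one). Subtracting the two lengths cancels
the unknown diameter:

$$v = \frac{(L_1 - L_2)\,p}{t_1 - t_2},$$

implemented in `estimate_velocity()`. Because $L_1, L_2$ are integer
pixel counts, velocity is quantized with step
$p/(t_1 - t_2)$ (`velocity_resolution()`), about $2.82\times10^{-4}$
m/s at the default optics (0.704 µm/px, 4994/2500 µs). The estimator
depends only on the differences $(\Delta L, \Delta t)$; a negative
$\Delta L$ signals a mismatched pair or noise and is raised as an
error rather than clamped, so data-quality problems stay visible.

Once $v$ is known, the streak length in each channel is
$\Delta = \operatorname{round}(v\,t/p)$ pixels
(`compute_elongation()`; rounding is half-away-from-zero so that a
9.988-px elongation becomes the 10-px lift the arithmetic implies).
The **lift** operator (`restore_lift()`) removes, in every image
column, the $\Delta$ downstream-most foreground pixels of the
(downstream-most) foreground run and max-merges their gray values
$\Delta$ rows upstream; the restored support is the original support
eroded by a downstream segment of length $\Delta$. For any *Y-convex*
support — every column a single contiguous run, which includes disks —
this exactly inverts the sweep. Values whose destination would fall
upstream of the run are discarded: the restored support must not grow
beyond the erosion, otherwise lateral columns (where the run is
shorter than $2\Delta$) would smear upstream. A run no longer than
$\Delta$ collapses to its upstream-most pixel with a warning.

The conventional baseline (`restore_compress()`) rescales the crop
axially by $(L-\Delta)/L$ with nearest-neighbor sampling. It recovers
the streak *length* but maps the streaked outline, not the swept
support, so a streaked disk returns as a flattened blob — the failure
mode that motivates the lift. (A published account of this baseline
quotes a magnification, an elongated length and a restored length that
are mutually inconsistent; the package uses the self-consistent factor
$(L-\Delta)/L$ throughout.)

## The synthetic forward model

Real acquisitions from the original optical bench are not available,
so `render_blurred_particle()` replaces the hardware with an analytic
camera model: each pixel's intensity is the particle's peak contrast
times the *fraction of the exposure* during which the moving disk
covers the pixel center, quantized to 8 bits. For a pixel at lateral
offset $dx$ from the particle axis and chord half-length
$h = \sqrt{R^2 - dx^2}$, that fraction is the overlap of
$[y-h,\,y+h]$ with the center's sweep $[c_y,\,c_y + vt]$, divided by
$vt$ — a closed-form 1-D integral, evaluated per column. A deliberately
independent reference renderer
(`render_blurred_particle_oracle()`) instead averages the stationary
disk indicator over $n$ equally spaced sub-instants (midpoint rule)
and is used only in tests. The equivalence tests run the oracle at 400
sub-steps: for an indicator function the midpoint-sampling error is
bounded by $1/n$ of the intensity range, so 100 steps could disagree
with the analytic integral by up to 2.6 of 256 levels, while 400 steps
guarantee agreement within one level after quantization.

Modeling choices, fixed once:

* **Axes.** Flow maps to image rows, downstream = increasing row
  index; the streak extends downstream of the exposure-start position.
  Columns are the cross-flow (X) axis.
* **Sub-pixel geometry.** Particle centers are continuous; coverage is
  decided at pixel centers, so nothing is locked to the grid.
* **Noise.** Additive Gaussian, clipped to the bit depth, drawn per
  channel from the scene's seeded RNG (`flow_scene(noise_sigma=)`).
  The default is noise-free; the model contains no PSF, defocus,
  wavelength-dependent contrast or readout artifacts, so passing tests
  demonstrate correctness of the measurement chain, not robustness to
  real optics.
* **Scenes.** `laminar_scene()` places particles across a channel of
  width $w$ (default 73.9 µm, depth 19.9 µm) and assigns each the
  parabolic no-slip profile $v(x) = v_{max}\,4x(w-x)/w^2$
  (`laminar_velocity()`). Default particles are 12-µm disks, the
  reference polystyrene beads. Axial spacing defaults to the
  collision-free separation (below), so a rendered scene is measurable
  without crowding flags.

## The measurement chain

`measure_scene_velocities()` runs the published program order:
background subtraction (clamped at zero), binarization, morphological
cleanup, 8-connected component labeling, per-component morphometry,
cross-channel matching, then the velocity estimate per pair.

* **Threshold.** `binarize()` marks foreground strictly above the
  threshold. Two policies exist. `"half-contrast"` places the
  threshold halfway between the crop's minimum and maximum; under the
  linear-ramp edges of the coverage model this selects the ≥50 %
  temporal-coverage region, whose flow-axis extent equals the
  *stationary* diameter for every velocity (the ramp steepens but its
  midpoint stays $\pm R$ around the mid-sweep center) — useful for
  size estimates of moving particles, useless for velocimetry, since
  $L_1 - L_2 = 0$ identically. The measurement chain therefore
  defaults to the *support* threshold (0): every pixel the particle
  covered at any instant is foreground, which makes
  $L = d + vt/p$ hold to ±1 px and preserves the full differential
  signal. With noisy images a small positive threshold should be used
  instead; the choice is exposed as a parameter.
* **Cleanup.** One opening + closing with a 3×3 cross (`clean_mask()`),
  the minimal pair that erases isolated pixels and fills single-pixel
  cracks. The mask is padded before morphology so the structuring
  element never interacts with the image border (EBImage's border
  handling would otherwise grow objects against the edge). On a
  rasterized 21-px disk the opening shaves at most one lone
  edge-protrusion pixel; extents are unaffected.
* **Labeling.** 8-connected, the blob-extraction standard:
  `EBImage::bwlabel()` (4-connected) followed by union-find merging of
  diagonally adjacent labels. Bounding boxes are half-open, 0-based,
  so extent = bound difference with no ±1 ambiguity.
* **Flags.** Components touching the border (`truncated`) or whose
  80×80-px analysis crop would contain another component (`crowded`)
  are excluded from velocimetry.
* **Matching.** Channels are co-registered, so `match_particles()`
  pairs components greedily by centroid-column distance, tie-broken by
  the upstream bounding-box edge (the exposure-start edge, which the
  two channels share) and then by smaller row; candidates beyond
  `tol_px` (default 10 px) never pair.

`fit_flow_profile()` is an ordinary least-squares quadratic
(`stats::lm`) returning a classed object with `print`/`coef`/`predict`
methods; $R^2 = 1 - SS_{res}/SS_{tot}$, defined as 0 when the response
has zero variance (constant velocities are legal input), and a
degenerate design (a single distinct $x$) is an error.

## Feasibility calculators

`max_irradiation_time()` is the exposure during which a particle
travels one pixel, $p/v$: the longest irradiation that freezes the
shape. `min_separation()` is the axial spacing below which two
particles can share one analysis crop: crop span + one diameter + the
streak $v t$. `max_density()` converts that spacing to a volumetric
density by dividing one particle over the volume (separation ×
effective cross-section), with the cross-section the channel depth
times $k$ standard deviations of the focused stream's lateral position
(defaults 19.9 µm depth, SD 5.31 µm at mean 34.4 µm, $k = 4 \approx$
95 % of a Gaussian stream). The separation→density conversion is not
uniquely determined by the physics; this product form is the package's
model, all constants are configurable (`density_config()`), and
results should be read as model-dependent. At the resulting density a
memoryless (Poisson) arrival stream would still place ~63 % of
consecutive pairs closer than the minimum separation — the calculator
expresses the densest *orderly* loading, i.e. the guarantee that
spacings ≥ `min_separation()` are collision-free, which is what the
property tests verify.

## Problem sizes and numerical conventions

The test and acceptance workloads are sized for interactive runs:
velocity-recovery sweeps use 12 velocities spanning 0.25–3.0 mm/s on
single-particle fields; support-recovery checks the full grid of disk
diameters 8–30 px × shifts 0–15 px; oracle-equivalence uses a 20-case
diameter × velocity grid at 400 sub-steps; laminar-scene tests use 5–7
particles in a 73.9-µm channel. The area-flatness sweep runs on the
estimator's quantization grid $k \cdot p/(t_1-t_2)$, $k = 1..10$: these
are the velocities the method itself can report — in the real chain the
lift is always driven by such an estimate — and on that grid the streak
length is within 0.03 px of the integer lift, so the corrected area is
velocity-invariant to well under the ±1 px/column rasterization bound.
Off-grid velocities leave a systematic sub-pixel residual of up to
±0.5 px per occupied column (≈ ±17 px on a 12-µm disk), which is a
quantization property of integer-pixel lifting, not an implementation
artifact.

Other conventions: intensities quantize by rounding to the nearest
level with clipping; Δ rounds half away from zero; greyscale merge on
lift copy-back takes the maximum (preserves the longer-coverage
evidence); non-Y-convex columns lift only their downstream-most run;
empty masks, empty scenes and empty match sets are legal and propagate
as zero-row results.

## Known limitations

* The forward model is 2-D and PSF-free: no defocus with channel
  depth, no wavelength-dependent contrast between the two channels, no
  shot/readout noise structure. Agreement on synthetic scenes bounds
  algorithmic correctness only.
* Velocity is quantized at $p/(t_1-t_2)$; sub-step velocities are
  indistinguishable by construction.
* The lift is exact only for Y-convex supports; textured or concave
  cells violate that premise column-wise, and only the downstream run
  is corrected.
* Touching or overlapping particles are flagged and skipped, not
  split; there is no watershed stage.
* The density limit inherits the stream-model assumptions above.
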