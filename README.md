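# flowblur

Single-shot velocimetry and shape restoration for imaging flow cytometry,
based on simultaneous two-wavelength acquisition with two different
exposure times.

## The problem

In imaging flow cytometry, cells and beads move through a microchannel
while the camera shutter is open, so every particle image is smeared
into a motion streak along the flow axis. The streak corrupts
morphometry (length, cross-sectional area), and correcting it requires
the particle's velocity — which conventional systems obtain by tracking
particles across frames, costing temporal resolution and hardware
complexity.

The method implemented here needs only **one** camera frame. Two light
sources of different wavelengths illuminate the channel simultaneously
with different irradiation times (t₁ = 4994 µs halogen, t₂ = 2500 µs
LED, both starting when the shutter opens), and a multi-view unit
splits the image by wavelength into two co-registered sub-images. A
particle of stationary diameter *d* moving at velocity *v* appears with
binarized flow-axis length L = d + v·t/p in a channel exposed for time
*t* (pixel size *p*), so its velocity follows from the *difference* of
the two lengths, independent of the particle's size:

```
v = (L1 − L2) · p / (t1 − t2)
```

with quantization resolution p/(t₁ − t₂) ≈ 0.282 mm/s per pixel at the
default optics. The known elongation Δ = round(v·t/p) is then undone by
the **lift** operator: in every image column, the downstream Δ
foreground pixels are removed and their gray values copied Δ rows
upstream, which exactly inverts the streak (a disk ⊕ segment Minkowski
sum) for any Y-convex shape. The conventional baseline — compressing
the crop axially by (L − Δ)/L — recovers only the length, not the
outline, and is included for comparison.

Because the original study's raw image data are not available, the
package ships an analytic forward model of the dual-exposure optics
(temporal-coverage rendering of moving disks, with a brute-force
temporal-supersampling oracle for verification), so every stage of the
measurement chain is testable end-to-end against known ground truth.

## Worked example

```r
library(flowblur)
opt <- optics_config()   # 0.704 um/px, 4994/2500 us, 80x80 px crops

# the reference worked example: lengths 28 px and 23 px
estimate_velocity(28, 23, opt)
#> velocity 1.411e-03 m/s (1.411 mm/s), dL = 5 px, step 2.823e-04 m/s

compute_elongation(1.411e-3, opt$exposure_long_us, opt)
#> elongation 7.05 um = 10 px (v = 1.411e-03 m/s, t = 4994 us)

# synthesize a 5-particle laminar scene and measure it in one shot
scene <- laminar_scene(n = 5, v_max_mps = 2e-3)
imgs  <- render_dual_channel(scene, opt)
vel   <- measure_scene_velocities(imgs$long, imgs$short, opt)
vel[, c("x_position_um", "L1_px", "L2_px", "velocity_mm_s")]
#>   x_position_um L1_px L2_px velocity_mm_s
#> 1       7.25644    22    19     0.8468324
#> 2      52.17786    29    23     1.6936648
#> 3      22.43000    29    23     1.6936648
#> 4      67.34782    22    20     0.5645549
#> 5      37.31200    31    24     1.9759423

fit_flow_profile(vel$x_position_um, vel$velocity_mm_s)
#> Laminar flow profile (quadratic OLS fit)
#>   v(x) = -0.001426 x^2 + 0.1026 x + 0.1529
#>   R^2 = 0.994 on 5 particles
#>   vertex (profile maximum) at x = 35.98 um, v = 1.998
```

Each row is one particle: its position across the 73.9-µm channel, its
streak lengths in the long- and short-exposure channels, and the
velocity from their difference. The quadratic fit recovers the
parabolic laminar profile with its 2 mm/s center-line maximum to within
the quantization step.

Feasibility calculators bound the operating regime (1-px-travel
irradiation time; collision-free axial spacing and the model-dependent
maximum sample density):

```r
limits_table(c(5e-4, 1e-3, 2e-3))
#>   velocity_mps max_irradiation_time_us min_separation_um max_density_per_ml
#> 1        5e-04                    1408            70.817           33408339
#> 2        1e-03                     704            73.314           32270485
#> 3        2e-03                     352            78.308           30212473
```

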