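# Shared fixtures: default optics and convenience renders.

opt_default <- optics_config()

# Diameter (um) whose rasterized disk spans exactly d_px pixel centers
# when centered mid-pixel: slightly under d_px * pixel_size so the edge
# pixels' centers fall strictly inside.
diameter_for_px <- function(d_px, optics = opt_default) {
  d_px * optics$pixel_size_um - 0.01
}

# Velocity (m/s) for which v * exposure spans exactly s_px pixels.
velocity_for_px <- function(s_px, exposure_us, optics = opt_default) {
  s_px * optics$pixel_size_um / exposure_us
}

# Single-particle dual render: particle centered in a field large enough
# for the longest streak.
render_pair <- function(velocity_mps, diameter_um = 12,
                        optics = opt_default) {
  r <- diameter_um / 2
  streak <- velocity_mps * optics$exposure_long_us
  rows <- ceiling((2 * r + streak + 16) / optics$pixel_size_um)
  sp <- particle_spec(center_x_um = 28, center_y_um = r + 5,
                      diameter_um = diameter_um,
                      velocity_mps = velocity_mps)
  list(long = render_blurred_particle(sp, optics$exposure_long_us, optics,
                                      c(rows, 80)),
       short = render_blurred_particle(sp, optics$exposure_short_us,
                                       optics, c(rows, 80)),
       spec = sp)
}
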