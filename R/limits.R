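#' Particle-density model configuration
#'
#' Parameters of the feasibility calculators: the analysis crop, the
#' particle size, the exposure used for the streak allowance, the
#' channel depth and the measured cross-flow distribution of the
#' hydrodynamically focused sample stream (mean and SD of the X
#' position). The effective stream width is taken as `k` standard
#' deviations (k = 4 covers ~95% of a Gaussian-focused stream).
#'
#' @param crop_px Analysis crop side, px.
#' @param particle_diameter_um Particle diameter, um.
#' @param exposure_us Irradiation time used for the streak term, us.
#' @param channel_depth_um Channel depth, um.
#' @param stream_mean_x_um Mean cross-flow position of the stream, um.
#' @param stream_sd_x_um SD of the cross-flow position, um.
#' @param stream_width_multiplier Effective stream width in SD units.
#' @return An object of class `"density_config"`.
#' @export
density_config <- function(crop_px = 80, particle_diameter_um = 12,
                           exposure_us = 4994, channel_depth_um = 19.9,
                           stream_mean_x_um = 34.4, stream_sd_x_um = 5.31,
                           stream_width_multiplier = 4) {
  vals <- c(crop_px, particle_diameter_um, exposure_us, channel_depth_um,
            stream_mean_x_um, stream_sd_x_um, stream_width_multiplier)
  if (any(vals <= 0)) stop("all density-model parameters must be positive")
  structure(list(crop_px = crop_px,
                 particle_diameter_um = particle_diameter_um,
                 exposure_us = exposure_us,
                 channel_depth_um = channel_depth_um,
                 stream_mean_x_um = stream_mean_x_um,
                 stream_sd_x_um = stream_sd_x_um,
                 stream_width_multiplier = stream_width_multiplier),
            class = "density_config")
}

#' Maximum irradiation time before visible elongation
#'
#' The exposure for which a particle moves exactly one pixel: longer
#' irradiation produces a measurable streak, shorter freezes the shape.
#' `t_max = pixel_size / velocity`.
#'
#' @param velocity_mps Particle velocity, m/s (> 0).
#' @param optics An [optics_config()].
#' @return Maximum irradiation time in microseconds (vectorized).
#' @export
max_irradiation_time <- function(velocity_mps, optics = optics_config()) {
  if (any(velocity_mps <= 0))
    stop("velocity must be > 0 (the 1-px time is unbounded at rest)")
  optics$pixel_size_um / velocity_mps  # um / (m/s) = us
}

#' Minimum axial separation preventing crop collisions
#'
#' The flow-axis distance below which two neighboring particles can
#' appear in the same analysis crop: the crop span plus one particle
#' diameter plus the motion streak `velocity * exposure`.
#'
#' @param velocity_mps Particle velocity, m/s (>= 0).
#' @param cfg A [density_config()].
#' @param optics An [optics_config()].
#' @return Minimum separation in micrometers (vectorized).
#' @export
min_separation <- function(velocity_mps, cfg = density_config(),
                           optics = optics_config()) {
  stopifnot(all(velocity_mps >= 0), inherits(cfg, "density_config"))
  cfg$crop_px * optics$pixel_size_um + cfg$particle_diameter_um +
    velocity_mps * cfg$exposure_us
}

#' Maximum particle density before crop collisions
#'
#' Converts the minimum axial separation into a volumetric density by
#' dividing one particle over the volume `min_separation x
#' effective_cross_section`, with the effective cross-section the
#' channel depth times the effective stream width (`k` SDs of the
#' focused stream's X distribution). The conversion is model-dependent:
#' it assumes particles confined to the focused stream and expresses
#' the densest loading at which successive particles can keep the
#' collision-free spacing.
#'
#' @inheritParams min_separation
#' @return Maximum density in particles per mL (vectorized).
#' @export
max_density <- function(velocity_mps, cfg = density_config(),
                        optics = optics_config()) {
  sep <- min_separation(velocity_mps, cfg, optics)
  cross <- cfg$channel_depth_um *
    (cfg$stream_width_multiplier * cfg$stream_sd_x_um)
  1 / (sep * cross) * 1e12  # um^-3 -> mL^-1
}

#' Feasibility table over a velocity grid
#'
#' @param velocities_mps Velocity grid, m/s.
#' @inheritParams min_separation
#' @return Data frame with columns `velocity_mps`,
#'   `max_irradiation_time_us`, `min_separation_um`,
#'   `max_density_per_ml`.
#' @export
limits_table <- function(velocities_mps, cfg = density_config(),
                         optics = optics_config()) {
  data.frame(velocity_mps = velocities_mps,
             max_irradiation_time_us =
               max_irradiation_time(velocities_mps, optics),
             min_separation_um =
               min_separation(velocities_mps, cfg, optics),
             max_density_per_ml =
               max_density(velocities_mps, cfg, optics))
}
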