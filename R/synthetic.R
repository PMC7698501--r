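#' Particle specification for the synthetic forward model
#'
#' Ground-truth description of one particle: position of its center at
#' the start of the exposure (in micrometers, image coordinates: x across
#' the flow, y along the flow with downstream = increasing y/row),
#' diameter, speed along the flow axis and peak image contrast.
#'
#' @param center_x_um,center_y_um Center position at exposure start, um.
#' @param diameter_um Particle diameter in micrometers (12 um polystyrene
#'   beads are the reference sample).
#' @param velocity_mps Speed along the flow axis in m/s (>= 0).
#' @param intensity Peak intensity above background, in levels.
#' @return An object of class `"particle_spec"`.
#' @export
particle_spec <- function(center_x_um, center_y_um, diameter_um = 12,
                          velocity_mps = 0, intensity = 200) {
  stopifnot(diameter_um > 0, velocity_mps >= 0, intensity >= 0)
  structure(list(center_x_um = center_x_um, center_y_um = center_y_um,
                 diameter_um = diameter_um, velocity_mps = velocity_mps,
                 intensity = intensity),
            class = "particle_spec")
}

#' Multi-particle scene for dual-channel synthesis
#'
#' A scene is a list of particles flowing in a microchannel of given
#' width (x, columns) imaged over a field of given axial length (y,
#' rows), with a background level and optional additive Gaussian noise.
#'
#' @param particles List of [particle_spec()] objects.
#' @param channel_width_um Channel (pathway) width across the flow, um.
#' @param field_length_um Axial length of the rendered field, um.
#' @param channel_depth_um Channel depth, um (metadata only; the image is
#'   a 2-D projection).
#' @param background_level Baseline intensity in levels.
#' @param noise_sigma SD of additive Gaussian noise in levels (>= 0).
#' @param rng_seed Integer seed controlling the noise draws.
#' @return An object of class `"flow_scene"`.
#' @export
flow_scene <- function(particles = list(), channel_width_um = 73.9,
                       field_length_um = 180, channel_depth_um = 19.9,
                       background_level = 0, noise_sigma = 0,
                       rng_seed = 1L) {
  stopifnot(noise_sigma >= 0, channel_width_um > 0, field_length_um > 0)
  if (inherits(particles, "particle_spec")) particles <- list(particles)
  for (p in particles) {
    stopifnot(inherits(p, "particle_spec"))
    r <- p$diameter_um / 2
    if (p$center_x_um < r || p$center_x_um > channel_width_um - r)
      stop("particle center x = ", p$center_x_um,
           " um does not fit within the channel width")
    if (p$center_y_um < r)
      stop("particle center y = ", p$center_y_um,
           " um extends above the rendered field")
  }
  structure(list(particles = particles,
                 channel_width_um = channel_width_um,
                 field_length_um = field_length_um,
                 channel_depth_um = channel_depth_um,
                 background_level = background_level,
                 noise_sigma = noise_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "flow_scene")
}

#' Build a laminar scene of particles on the parabolic flow profile
#'
#' Places `n` particles at given (or evenly spaced) positions across the
#' channel width, assigning each the local laminar velocity
#' [laminar_velocity()] for the given center-line maximum.
#'
#' @param n Number of particles.
#' @param v_max_mps Center-line maximum velocity, m/s.
#' @param x_positions_um Optional positions across the width; defaults to
#'   evenly spaced interior positions.
#' @param y_positions_um Optional axial start positions; the default is
#'   a ladder spaced by the collision-free separation (crop span +
#'   diameter + longest streak), so no particle is flagged crowded.
#' @param optics Optics used to size the default ladder spacing.
#' @inheritParams flow_scene
#' @inheritParams particle_spec
#' @return A `"flow_scene"`.
#' @export
laminar_scene <- function(n = 5, v_max_mps = 2e-3,
                          channel_width_um = 73.9,
                          diameter_um = 12,
                          x_positions_um = NULL, y_positions_um = NULL,
                          field_length_um = NULL,
                          noise_sigma = 0, rng_seed = 1L,
                          optics = optics_config(), ...) {
  r <- diameter_um / 2
  if (is.null(x_positions_um))
    x_positions_um <- seq(r + 1, channel_width_um - r - 1, length.out = n)
  if (is.null(y_positions_um)) {
    spacing <- optics$crop_px * optics$pixel_size_um + diameter_um +
      v_max_mps * optics$exposure_long_us + 2
    y_positions_um <- r + 2 + seq(0, by = spacing, length.out = n)
  }
  if (is.null(field_length_um))
    field_length_um <- max(y_positions_um) + r +
      v_max_mps * 1e6 * 5100e-6 + 10  # room for the longest streak
  parts <- Map(function(x, y) {
    particle_spec(center_x_um = x, center_y_um = y,
                  diameter_um = diameter_um,
                  velocity_mps = laminar_velocity(x, channel_width_um,
                                                  v_max_mps))
  }, x_positions_um, y_positions_um)
  flow_scene(parts, channel_width_um = channel_width_um,
             field_length_um = field_length_um,
             noise_sigma = noise_sigma, rng_seed = rng_seed, ...)
}

#' Parabolic laminar (Poiseuille) velocity profile
#'
#' Velocity across the channel width: zero at the walls, maximal at the
#' center, `v(x) = v_max * 4 x (w - x) / w^2`.
#'
#' @param x_um Position across the width, 0 <= x <= width.
#' @param width_um Channel width, um.
#' @param v_max_mps Center-line velocity, m/s.
#' @return Velocity in m/s (vectorized over `x_um`).
#' @export
laminar_velocity <- function(x_um, width_um, v_max_mps) {
  if (any(x_um < 0 | x_um > width_um))
    stop("x_um outside the channel [0, ", width_um, "]")
  v_max_mps * 4 * x_um * (width_um - x_um) / width_um^2
}

# Per-column analytic temporal coverage of a disk translating along the
# rows during the exposure. Returns the fraction of the exposure during
# which the moving disk covers each pixel center.
#
# Pixel centers: row i at y = (i - 0.5) * p, column j at x = (j - 0.5) * p.
# The disk center moves from (cx, cy) to (cx, cy + v * t).
coverage_fraction <- function(spec, exposure_us, optics, field_shape) {
  p <- optics$pixel_size_um
  nr <- field_shape[1]; nc <- field_shape[2]
  R <- spec$diameter_um / 2
  s_um <- spec$velocity_mps * exposure_us  # v [m/s] * t [us] = um
  cx <- spec$center_x_um; cy0 <- spec$center_y_um
  cy1 <- cy0 + s_um

  ycent <- (seq_len(nr) - 0.5) * p
  xcent <- (seq_len(nc) - 0.5) * p
  out <- matrix(0, nr, nc)
  dx <- xcent - cx
  hit <- which(abs(dx) <= R)
  if (!length(hit)) return(out)
  for (j in hit) {
    h <- sqrt(R^2 - dx[j]^2)
    if (s_um == 0) {
      out[, j] <- as.numeric(abs(ycent - cy0) <= h)
    } else {
      # pixel center y is covered while the disk center lies in
      # [y - h, y + h]; the center sweeps [cy0, cy1]
      ov <- pmin(ycent + h, cy1) - pmax(ycent - h, cy0)
      out[, j] <- pmax(0, ov) / s_um
    }
  }
  out
}

#' Render a motion-blurred particle image (analytic temporal coverage)
#'
#' Renders a single disk translating downstream during the exposure.
#' Each pixel's intensity is the particle's peak intensity times the
#' fraction of the exposure during which the moving disk covers the
#' pixel center, quantized to the configured bit depth. The nonzero
#' support is therefore the stationary disk swept along the flow axis by
#' `velocity * exposure` (a disk + segment Minkowski sum), rasterized at
#' pixel centers.
#'
#' @param spec A [particle_spec()].
#' @param exposure_us Exposure time in microseconds.
#' @param optics An [optics_config()].
#' @param field_shape `c(rows, cols)` of the output image.
#' @return Integer matrix (grayscale image; rows = flow axis).
#' @seealso [render_blurred_particle_oracle()] for the brute-force
#'   temporal-supersampling reference renderer.
#' @export
render_blurred_particle <- function(spec, exposure_us, optics,
                                    field_shape) {
  stopifnot(inherits(spec, "particle_spec"),
            inherits(optics, "optics_config"), exposure_us >= 0)
  p <- optics$pixel_size_um
  R <- spec$diameter_um / 2
  s_um <- spec$velocity_mps * exposure_us
  ylim <- field_shape[1] * p
  xlim <- field_shape[2] * p
  over_y <- max(R - spec$center_y_um,
                spec$center_y_um + s_um + R - ylim, 0)
  over_x <- max(R - spec$center_x_um, spec$center_x_um + R - xlim, 0)
  if (over_y > 1e-9 || over_x > 1e-9)
    stop(sprintf(
      "particle exits the field during the exposure (overrun %.3g um)",
      max(over_y, over_x)))
  f <- coverage_fraction(spec, exposure_us, optics, field_shape)
  quantize_intensity(f * spec$intensity, optics$bit_depth)
}

#' Brute-force temporal-supersampling renderer (reference oracle)
#'
#' Reference implementation of the blur model by explicit temporal
#' integration: the stationary disk indicator at pixel centers is
#' averaged over `n_steps` equally spaced sub-instants of the exposure
#' (midpoint rule). Slower than [render_blurred_particle()] but makes no
#' use of the analytic coverage integral; kept as an independent check.
#'
#' @inheritParams render_blurred_particle
#' @param n_steps Number of temporal sub-steps (>= 100 recommended).
#' @return Integer matrix (grayscale image).
#' @export
render_blurred_particle_oracle <- function(spec, exposure_us, optics,
                                           field_shape, n_steps = 400) {
  stopifnot(n_steps >= 1)
  p <- optics$pixel_size_um
  nr <- field_shape[1]; nc <- field_shape[2]
  R <- spec$diameter_um / 2
  ycent <- (seq_len(nr) - 0.5) * p
  xcent <- (seq_len(nc) - 0.5) * p
  dx2 <- outer(rep(1, nr), (xcent - spec$center_x_um)^2)
  acc <- matrix(0, nr, nc)
  s_um <- spec$velocity_mps * exposure_us
  for (k in seq_len(n_steps)) {
    cy <- spec$center_y_um + s_um * (k - 0.5) / n_steps
    dy2 <- outer((ycent - cy)^2, rep(1, nc))
    acc <- acc + (dx2 + dy2 <= R^2)
  }
  quantize_intensity(acc / n_steps * spec$intensity, optics$bit_depth)
}

#' Render the two simultaneous channel images of a scene
#'
#' Produces the co-registered long-exposure and short-exposure images of
#' the same scene. Both exposures start at the same instant, so the
#' short-exposure streak is a prefix of the long-exposure streak.
#' Additive Gaussian noise (if configured) is drawn independently per
#' channel from the scene's seeded RNG.
#'
#' @param scene A [flow_scene()].
#' @param optics An [optics_config()].
#' @return A list with integer-matrix elements `long` and `short`.
#' @export
render_dual_channel <- function(scene, optics) {
  stopifnot(inherits(scene, "flow_scene"),
            inherits(optics, "optics_config"))
  p <- optics$pixel_size_um
  shape <- c(ceiling(scene$field_length_um / p),
             ceiling(scene$channel_width_um / p))
  render_one <- function(exposure_us) {
    acc <- matrix(0, shape[1], shape[2])
    for (sp in scene$particles) {
      f <- coverage_fraction(sp, exposure_us, optics, shape)
      R <- sp$diameter_um / 2
      s_um <- sp$velocity_mps * exposure_us
      if (sp$center_y_um + s_um + R > scene$field_length_um + 1e-9)
        stop(sprintf(
          "particle exits the field during the exposure (overrun %.3g um)",
          sp$center_y_um + s_um + R - scene$field_length_um))
      acc <- pmax(acc, f * sp$intensity)  # particles do not overlap in use
    }
    acc + scene$background_level
  }
  long <- render_one(optics$exposure_long_us)
  short <- render_one(optics$exposure_short_us)
  if (scene$noise_sigma > 0) {
    rs <- .Random.seed_save()
    on.exit(.Random.seed_restore(rs), add = TRUE)
    set.seed(scene$rng_seed)
    long <- long + stats::rnorm(length(long), 0, scene$noise_sigma)
    short <- short + stats::rnorm(length(short), 0, scene$noise_sigma)
  }
  list(long = quantize_intensity(long, optics$bit_depth),
       short = quantize_intensity(short, optics$bit_depth))
}

# Save/restore the global RNG state so seeded noise draws do not disturb
# the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
  invisible()
}
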