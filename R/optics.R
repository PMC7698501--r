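#' Optics configuration for dual-exposure acquisition
#'
#' Bundles the acquisition parameters of the two-wavelength system: the
#' camera pixel size, the two simultaneous exposure (irradiation) times,
#' the frame interval, the side length of the per-particle analysis crop
#' and the intensity bit depth. The short exposure starts at the same
#' instant as the long one (both light pulses are synchronized with the
#' shutter opening), so the short exposure is a temporal prefix of the
#' long one.
#'
#' @param pixel_size_um Pixel size in micrometers per pixel.
#' @param exposure_long_us Long (halogen-channel) exposure time in
#'   microseconds.
#' @param exposure_short_us Short (LED-channel) exposure time in
#'   microseconds. Must be positive and strictly less than
#'   `exposure_long_us`.
#' @param frame_interval_us Image acquisition interval in microseconds;
#'   the long exposure cannot exceed it.
#' @param crop_px Side length, in pixels, of the square crop cut around
#'   each particle for analysis.
#' @param bit_depth Number of intensity levels (256 for 8-bit images).
#'
#' @return An object of class `"optics_config"`: a list with the above
#'   fields.
#'
#' @examples
#' opt <- optics_config()
#' opt$pixel_size_um
#' velocity_resolution(opt)  # m/s per 1-px elongation difference
#'
#' @export
optics_config <- function(pixel_size_um = 0.704,
                          exposure_long_us = 4994,
                          exposure_short_us = 2500,
                          frame_interval_us = 5000,
                          crop_px = 80,
                          bit_depth = 256) {
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1,
            is.numeric(exposure_long_us), is.numeric(exposure_short_us),
            is.numeric(frame_interval_us), is.numeric(crop_px),
            is.numeric(bit_depth))
  if (pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  if (!(exposure_short_us > 0 && exposure_short_us < exposure_long_us &&
        exposure_long_us <= frame_interval_us))
    stop("exposure times must satisfy 0 < exposure_short_us < ",
         "exposure_long_us <= frame_interval_us")
  if (crop_px < 1)
    stop("crop_px must be >= 1")
  if (bit_depth < 2)
    stop("bit_depth must be >= 2")
  structure(list(pixel_size_um = pixel_size_um,
                 exposure_long_us = exposure_long_us,
                 exposure_short_us = exposure_short_us,
                 frame_interval_us = frame_interval_us,
                 crop_px = as.integer(crop_px),
                 bit_depth = as.integer(bit_depth)),
            class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat("Dual-exposure optics configuration\n")
  cat(sprintf("  pixel size      : %.4g um/px\n", x$pixel_size_um))
  cat(sprintf("  exposures       : %g / %g us (long / short)\n",
              x$exposure_long_us, x$exposure_short_us))
  cat(sprintf("  frame interval  : %g us\n", x$frame_interval_us))
  cat(sprintf("  analysis crop   : %d x %d px\n", x$crop_px, x$crop_px))
  cat(sprintf("  bit depth       : %d levels\n", x$bit_depth))
  cat(sprintf("  velocity step   : %.3e m/s per px\n",
              velocity_resolution(x)))
  invisible(x)
}

#' Velocity quantization step of the dual-exposure estimator
#'
#' The smallest resolvable velocity, corresponding to a 1-px elongation
#' difference between the two channels: `p / (t1 - t2)` with `p` the
#' pixel size and `t1`, `t2` the two exposure times.
#'
#' @param optics An [optics_config()].
#' @return Velocity step in m/s.
#' @export
velocity_resolution <- function(optics) {
  stopifnot(inherits(optics, "optics_config"))
  optics$pixel_size_um / (optics$exposure_long_us - optics$exposure_short_us)
}

#' Convert between pixels and micrometers
#'
#' @param px,um Lengths in pixels / micrometers.
#' @param optics An [optics_config()].
#' @return Numeric vector of converted lengths.
#' @export
px_to_um <- function(px, optics) px * optics$pixel_size_um

#' @rdname px_to_um
#' @export
um_to_px <- function(um, optics) um / optics$pixel_size_um
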