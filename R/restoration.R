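#' Elongation of a streaked particle image
#'
#' The streak a particle leaves during one exposure has physical length
#' `velocity * exposure`; on the sensor it spans
#' `shift_px = round(shift_um / pixel_size)` pixels (rounding half away
#' from zero, so e.g. 9.988 px rounds to 10).
#'
#' @param velocity_mps Particle velocity, m/s (>= 0).
#' @param exposure_us Exposure (irradiation) time, us.
#' @param optics An [optics_config()].
#' @return An object of class `"elongation_spec"`: list with `shift_px`,
#'   `shift_um`, `exposure_us`, `velocity_mps`.
#' @examples
#' compute_elongation(1.69e-3, 4994)$shift_um  # 8.44 um
#' @export
compute_elongation <- function(velocity_mps, exposure_us,
                               optics = optics_config()) {
  stopifnot(velocity_mps >= 0, exposure_us >= 0,
            inherits(optics, "optics_config"))
  shift_um <- velocity_mps * exposure_us  # m/s * us = um
  structure(list(shift_px = as.integer(
                   round_half_away(shift_um / optics$pixel_size_um)),
                 shift_um = shift_um,
                 exposure_us = exposure_us,
                 velocity_mps = velocity_mps),
            class = "elongation_spec")
}

#' @export
print.elongation_spec <- function(x, ...) {
  cat(sprintf("elongation %.3g um = %d px (v = %.3e m/s, t = %g us)\n",
              x$shift_um, x$shift_px, x$velocity_mps, x$exposure_us))
  invisible(x)
}

# Foreground runs of one column: list of (start, end) row indices.
column_runs <- function(col) {
  fg <- col > 0
  if (!any(fg)) return(NULL)
  r <- rle(fg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Lift restoration of a streaked particle
#'
#' Inverts motion-streak elongation column by column: in every column
#' intersecting the particle, the downstream-most `shift_px` foreground
#' pixels are removed and their grayscale values copied back
#' `shift_px` rows upstream (merging by maximum). Each column's
#' foreground run is thereby shortened by the elongation from its
#' downstream end; for a particle whose support is an exact
#' disk + segment Minkowski sum (any Y-convex stationary shape), the
#' restored support is the stationary shape.
#'
#' Columns whose run is not longer than the shift collapse to their
#' upstream-most pixel, with a warning. In columns with several
#' foreground runs (non-convex shapes) only the downstream-most run is
#' shortened.
#'
#' @param image Grayscale or binary 0/1 matrix containing a single
#'   particle (one analysis crop).
#' @param spec An [compute_elongation()] result (or integer shift in px).
#' @return Matrix of the same type with the streak lifted.
#' @export
restore_lift <- function(image, spec) {
  assert_gray_image(image)
  shift <- if (inherits(spec, "elongation_spec")) spec$shift_px
           else as.integer(spec)
  stopifnot(shift >= 0)
  if (shift == 0) return(image)
  out <- image
  collapsed <- 0L
  for (j in seq_len(ncol(image))) {
    runs <- column_runs(image[, j])
    if (is.null(runs)) next
    run <- runs[nrow(runs), ]  # downstream-most run
    a <- run[["start"]]; b <- run[["end"]]
    if (b - a + 1 <= shift) {
      # run shorter than the shift: collapse to its upstream-most pixel
      keep <- max(image[a:b, j])
      out[a:b, j] <- 0
      out[a, j] <- keep
      collapsed <- collapsed + 1L
      next
    }
    src <- (b - shift + 1):b
    dst <- src - shift
    vals <- image[src, j]
    out[src, j] <- 0
    # copy back only within the remaining run: the restored support is
    # the original eroded by a shift-length downstream segment
    keep <- dst >= a
    if (any(keep))
      out[dst[keep], j] <- pmax(out[dst[keep], j], vals[keep])
  }
  if (collapsed > 0)
    warning(collapsed, " column run(s) shorter than the ", shift,
            "-px shift collapsed to a single pixel")
  storage.mode(out) <- storage.mode(image)
  out
}

#' Conventional compression restoration (baseline)
#'
#' The conventional correction rescales the streaked crop along the
#' flow axis by `(L - shift) / L`, with `L` the measured flow-axis
#' length, using nearest-neighbor interpolation; the cross-flow axis is
#' untouched. This recovers the streak length but not the true outline:
#' a streaked disk comes back as a flattened blob, which is the failure
#' mode the lift operator avoids.
#'
#' @param image Grayscale or binary matrix (single-particle crop).
#' @param spec An [compute_elongation()] result (or shift in px).
#' @param measured_length_px Measured flow-axis extent `L` of the
#'   particle, px; must exceed the shift.
#' @return Matrix with `round(nrow * (L - shift)/L)` rows.
#' @export
restore_compress <- function(image, spec, measured_length_px) {
  assert_gray_image(image)
  shift <- if (inherits(spec, "elongation_spec")) spec$shift_px
           else as.integer(spec)
  factor <- (measured_length_px - shift) / measured_length_px
  if (factor <= 0)
    stop("compression factor (L - shift)/L must be positive")
  if (factor == 1) return(image)
  nr <- nrow(image)
  nr_out <- max(1L, as.integer(round(nr * factor)))
  src <- pmin(nr, pmax(1L, ceiling((seq_len(nr_out) - 0.5) * nr / nr_out)))
  out <- image[src, , drop = FALSE]
  storage.mode(out) <- storage.mode(image)
  out
}

#' Motion-corrected cross-sectional area
#'
#' Area of the lift-restored mask, in pixels and square micrometers
#' (`um2 = px * pixel_size^2`). With the true elongation this is the
#' particle's stationary cross-sectional area, independent of its
#' velocity.
#'
#' @param mask Binary 0/1 matrix (single-particle crop).
#' @param spec An [compute_elongation()] result (or shift in px).
#' @param optics An [optics_config()].
#' @return List with `area_px`, `area_um2`, `raw_area_px`.
#' @export
corrected_area <- function(mask, spec, optics = optics_config()) {
  assert_binary_mask(mask)
  restored <- restore_lift(mask, spec)
  px <- sum(restored > 0)
  list(area_px = px,
       area_um2 = px * optics$pixel_size_um^2,
       raw_area_px = sum(mask > 0))
}
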