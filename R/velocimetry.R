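#' Velocity from the differential elongation of one particle
#'
#' The single-shot dual-exposure estimator: a particle moving at
#' velocity `v` leaves streaks of binarized flow-axis length
#' `L = d + v t / p` in a channel exposed for time `t` (with `d` its
#' stationary diameter and `p` the pixel size), so the difference of the
#' two simultaneous channel lengths gives
#' `v = (L1 - L2) p / (t1 - t2)` independent of the particle size.
#'
#' @param L1_px Flow-axis (Y) extent in the long-exposure channel, px.
#' @param L2_px Flow-axis (Y) extent in the short-exposure channel, px.
#' @param optics An [optics_config()].
#' @return An object of class `"velocity_estimate"`: list with
#'   `velocity_mps`, `elongation_diff_px`, `resolution_mps` (the 1-px
#'   quantization step `p/(t1-t2)`).
#' @examples
#' est <- estimate_velocity(28, 23, optics_config())
#' est$velocity_mps  # 1.41e-3 m/s
#' @export
estimate_velocity <- function(L1_px, L2_px, optics = optics_config()) {
  stopifnot(inherits(optics, "optics_config"),
            L1_px >= 1, L2_px >= 1)
  if (L1_px < L2_px)
    stop("negative elongation difference (L1 < L2): ",
         "mismatched particle pair or noise")
  dL <- L1_px - L2_px
  dt <- optics$exposure_long_us - optics$exposure_short_us
  structure(list(velocity_mps = dL * optics$pixel_size_um / dt,
                 elongation_diff_px = dL,
                 resolution_mps = velocity_resolution(optics)),
            class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("velocity %.3e m/s (%.3f mm/s), dL = %d px, step %.3e m/s\n",
              x$velocity_mps, x$velocity_mps * 1e3,
              as.integer(x$elongation_diff_px), x$resolution_mps))
  invisible(x)
}

#' Match particles between the two channel images
#'
#' Greedy nearest-neighbor pairing of per-channel measurements: pairs
#' are ranked by the centroid column (X) distance, ties broken by the
#' distance between the upstream (exposure-start) bounding-box edges and
#' then by smaller row. Candidates farther than `tol_px` in either
#' coordinate are never paired.
#'
#' @param long_meas,short_meas Measurement data frames from
#'   [extract_particles()] for the long- and short-exposure images.
#' @param tol_px Matching tolerance in pixels.
#' @return List with `pairs` (data frame of `label_long`, `label_short`)
#'   and `unmatched_long`, `unmatched_short` (label vectors).
#' @export
match_particles <- function(long_meas, short_meas, tol_px = 10) {
  if (nrow(long_meas) == 0 || nrow(short_meas) == 0)
    return(list(pairs = data.frame(label_long = integer(),
                                   label_short = integer()),
                unmatched_long = long_meas$label,
                unmatched_short = short_meas$label))
  cand <- expand.grid(i = seq_len(nrow(long_meas)),
                      j = seq_len(nrow(short_meas)))
  cand$dcol <- abs(long_meas$centroid_col[cand$i] -
                   short_meas$centroid_col[cand$j])
  cand$drow0 <- abs(long_meas$row0[cand$i] - short_meas$row0[cand$j])
  cand <- cand[cand$dcol <= tol_px & cand$drow0 <= tol_px, , drop = FALSE]
  cand <- cand[order(cand$dcol, cand$drow0, long_meas$row0[cand$i]), ,
               drop = FALSE]
  used_i <- logical(nrow(long_meas)); used_j <- logical(nrow(short_meas))
  pi <- integer(0); pj <- integer(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE; used_j[j] <- TRUE
      pi <- c(pi, i); pj <- c(pj, j)
    }
  }
  list(pairs = data.frame(label_long = long_meas$label[pi],
                          label_short = short_meas$label[pj]),
       unmatched_long = long_meas$label[!used_i],
       unmatched_short = short_meas$label[!used_j])
}

#' Measure all particle velocities in one dual-exposure shot
#'
#' Runs the full chain on a co-registered channel pair: background
#' subtraction, binarization, morphological cleanup, component
#' extraction, cross-channel matching, and the differential-elongation
#' velocity estimate per matched pair. Particles flagged truncated or
#' crowded in either channel are excluded.
#'
#' @param long_img,short_img Grayscale matrices of the long/short
#'   exposure channels.
#' @param optics An [optics_config()].
#' @param background Optional list with `long` and `short` background
#'   images; omitted means zero background.
#' @param threshold Binarization threshold or policy (see [binarize()]).
#'   The default `0` keeps every pixel the particle covered at any time
#'   during the exposure, which preserves the full streak length.
#' @param clean If `TRUE` (default) apply [clean_mask()] before
#'   measuring.
#' @param tol_px Matching tolerance for [match_particles()].
#' @return Data frame with one row per valid matched pair:
#'   `label_long`, `label_short`, `x_position_um` (centroid column of
#'   the long channel, in um), `L1_px`, `L2_px`, `velocity_mps`,
#'   `velocity_mm_s`, `resolution_mps`.
#' @export
measure_scene_velocities <- function(long_img, short_img,
                                     optics = optics_config(),
                                     background = NULL,
                                     threshold = 0, clean = TRUE,
                                     tol_px = 10) {
  if (!all(dim(long_img) == dim(short_img)))
    stop("channel images have different shapes")
  if (!is.null(background)) {
    long_img <- subtract_background(long_img, background$long)
    short_img <- subtract_background(short_img, background$short)
  }
  prep <- function(img) {
    m <- binarize(img, threshold)
    if (clean) m <- clean_mask(m)
    extract_particles(m, optics)
  }
  ml <- prep(long_img); ms <- prep(short_img)
  mm <- match_particles(ml, ms, tol_px)
  out <- data.frame(label_long = integer(), label_short = integer(),
                    x_position_um = numeric(), L1_px = integer(),
                    L2_px = integer(), velocity_mps = numeric(),
                    velocity_mm_s = numeric(), resolution_mps = numeric())
  for (k in seq_len(nrow(mm$pairs))) {
    il <- match(mm$pairs$label_long[k], ml$label)
    is <- match(mm$pairs$label_short[k], ms$label)
    if (ml$truncated[il] || ml$crowded[il] ||
        ms$truncated[is] || ms$crowded[is]) next
    est <- estimate_velocity(ml$y_extent_px[il], ms$y_extent_px[is],
                             optics)
    out[nrow(out) + 1, ] <- list(
      ml$label[il], ms$label[is],
      (ml$centroid_col[il] + 0.5) * optics$pixel_size_um,
      ml$y_extent_px[il], ms$y_extent_px[is],
      est$velocity_mps, est$velocity_mps * 1e3, est$resolution_mps)
  }
  out
}

#' Quadratic fit of the cross-channel laminar flow profile
#'
#' Ordinary least-squares fit of `v = a x^2 + b x + c` to per-particle
#' velocities against their position across the channel width. The
#' coefficient of determination uses `R^2 = 1 - SS_res/SS_tot`, defined
#' as 0 when the response has zero variance.
#'
#' @param x_positions_um Positions across the width, um.
#' @param velocities_mps Velocities (any consistent unit; coefficients
#'   come out in that unit).
#' @return An object of class `"flow_profile_fit"`: list with `a`, `b`,
#'   `c`, `r_squared`, `n_points` and the underlying `stats::lm` fit.
#' @export
fit_flow_profile <- function(x_positions_um, velocities_mps) {
  x <- as.numeric(x_positions_um); v <- as.numeric(velocities_mps)
  stopifnot(length(x) == length(v))
  if (length(x) < 3)
    stop("at least 3 points are required for a quadratic fit")
  if (length(unique(x)) < 2)
    stop("degenerate design: all x positions are equal")
  fit <- stats::lm(v ~ x + I(x^2))
  co <- stats::coef(fit)
  co[is.na(co)] <- 0
  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(a = unname(co["I(x^2)"]), b = unname(co["x"]),
                 c = unname(co["(Intercept)"]),
                 r_squared = r2, n_points = length(x), lm_fit = fit),
            class = "flow_profile_fit")
}

#' @export
print.flow_profile_fit <- function(x, digits = 4, ...) {
  cat("Laminar flow profile (quadratic OLS fit)\n")
  cat(sprintf("  v(x) = %s x^2 + %s x + %s\n",
              signif(x$a, digits), signif(x$b, digits),
              signif(x$c, digits)))
  cat(sprintf("  R^2 = %.3f on %d particles\n", x$r_squared, x$n_points))
  if (x$a < 0)
    cat(sprintf("  vertex (profile maximum) at x = %.2f um, v = %s\n",
                -x$b / (2 * x$a),
                signif(x$c - x$b^2 / (4 * x$a), digits)))
  invisible(x)
}

#' @export
coef.flow_profile_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' @export
predict.flow_profile_fit <- function(object, x_um, ...) {
  object$a * x_um^2 + object$b * x_um + object$c
}
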