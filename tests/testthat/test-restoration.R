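test_that("elongation converts velocity and exposure to a pixel shift", {
  opt <- optics_config()
  e <- compute_elongation(1.69e-3, 4994, opt)
  expect_equal(e$shift_um, 1.69e-3 * 4994)  # 8.44 um to 3 s.f.
  expect_equal(signif(e$shift_um, 3), 8.44)

  # 2 px/ms: 9.988 px rounds half-away-from-zero to 10; short gives 5
  v <- 2 * 0.704 / 1000  # 2 px/ms in m/s
  expect_equal(compute_elongation(v, 4994, opt)$shift_px, 10L)
  expect_equal(compute_elongation(v, 2500, opt)$shift_px, 5L)

  e0 <- compute_elongation(0, 4994, opt)
  expect_equal(e0$shift_px, 0L)
  expect_equal(e0$shift_um, 0)
  # invariant |shift_px - shift_um/p| <= 0.5
  expect_lte(abs(e$shift_px - e$shift_um / 0.704), 0.5)
})

test_that("lift restoration inverts the streak of Y-convex shapes", {
  opt <- optics_config()
  # zero shift is the identity
  img <- matrix(sample(0:255, 100, TRUE), 10, 10)
  expect_identical(restore_lift(img, compute_elongation(0, 4994, opt)), img)

  # full grid of disk diameters and shifts: support recovered exactly
  # (up to 1 px per column)
  for (d_px in c(8, 15, 21, 30)) {
    for (shift in c(0, 3, 9, 15)) {
      d <- diameter_for_px(d_px)
      v <- velocity_for_px(shift, 4994)
      rows <- ceiling((12 + d / 2 + (shift + 6) * 0.704) / 0.704)
      stat <- binarize(render_blurred_particle(
        particle_spec(20, 12, d, 0), 4994, opt, c(rows, 50)), 0)
      blur <- binarize(render_blurred_particle(
        particle_spec(20, 12, d, v), 4994, opt, c(rows, 50)), 0)
      lifted <- restore_lift(blur, compute_elongation(v, 4994, opt))
      per_col <- colSums(lifted != stat)
      expect_lte(max(per_col), 1)
    }
  }
})

test_that("the two channel crops restore to the same support", {
  opt <- optics_config()
  v <- 2 * 0.704 / 1000  # shifts of 10 px (long) and 5 px (short)
  pair <- render_pair(v, diameter_um = diameter_for_px(21))
  bl <- binarize(pair$long, 0); bs <- binarize(pair$short, 0)
  rl <- restore_lift(bl, compute_elongation(v, opt$exposure_long_us, opt))
  rs <- restore_lift(bs, compute_elongation(v, opt$exposure_short_us, opt))
  ml <- extract_particles(rl, opt); ms <- extract_particles(rs, opt)
  expect_equal(ml$y_extent_px, ms$y_extent_px)
  expect_equal(ml$y_extent_px, 21)
  # symmetric difference of the supports is <= 2 px per column
  expect_lte(max(colSums(rl != rs)), 2)
})

test_that("columns shorter than the shift collapse with a warning", {
  m <- matrix(0L, 10, 3)
  m[4:6, 2] <- 1L  # 3-px run, 5-px shift
  expect_warning(out <- restore_lift(m, 5L), "collapsed")
  expect_equal(which(out[, 2] > 0), 4)
})

test_that("compression rescales the flow axis only (baseline behavior)", {
  opt <- optics_config()
  img <- matrix(sample(0:255, 60, TRUE), 6, 10)
  expect_identical(restore_compress(img, 0L, 24), img)
  # factor 1/2 on a 2-row image gives a 1-row image
  two <- matrix(c(10L, 20L), 2, 1)
  expect_equal(nrow(restore_compress(two, 1L, 2)), 1)
  expect_error(restore_compress(two, 2L, 2), "positive")

  # correct shift recovers the streak length but not the disk outline
  d <- diameter_for_px(21)
  shift <- 8
  v <- velocity_for_px(shift, 4994)
  stat <- binarize(render_blurred_particle(
    particle_spec(20, 12, d, 0), 4994, opt, c(60, 50)), 0)
  blur <- binarize(render_blurred_particle(
    particle_spec(20, 12, d, v), 4994, opt, c(60, 50)), 0)
  mb <- extract_particles(blur, opt)
  comp <- restore_compress(blur, shift, mb$y_extent_px)
  mc <- extract_particles(comp, opt)
  expect_lte(abs(mc$y_extent_px - 21), 1)   # length recovered
  expect_equal(mc$x_extent_px, 21)          # width untouched
  # but the restored blob is not the stationary disk
  expect_gt(abs(mc$area_px - sum(stat)), 5)
})

test_that("lift-corrected area is velocity-invariant (flatness)", {
  opt <- optics_config()
  d <- diameter_for_px(17)
  # per-column loss: with all runs longer than the shift, the corrected
  # area equals raw - (occupied columns) * shift exactly
  v <- velocity_for_px(6, 4994)
  blur <- binarize(render_blurred_particle(
    particle_spec(20, 10, d, v), 4994, opt, c(50, 50)), 0)
  ca <- corrected_area(blur, compute_elongation(v, 4994, opt), opt)
  ncols <- sum(colSums(blur) > 0)
  expect_equal(ca$area_px, ca$raw_area_px - ncols * 6)
  expect_equal(ca$area_um2, ca$area_px * 0.704^2)

  # velocity sweep on the estimator's quantization grid (the velocities
  # the method itself reports, which drive the lift in practice): raw
  # grows, lift-corrected stays flat
  vs <- (1:7) * velocity_resolution(opt)
  raw <- lift <- comp <- numeric(length(vs))
  for (i in seq_along(vs)) {
    rows <- ceiling((10 + d / 2 + vs[i] * 4994 + 5) / 0.704)
    blur <- binarize(render_blurred_particle(
      particle_spec(20, 10, d, vs[i]), 4994, opt, c(rows, 50)), 0)
    spec <- compute_elongation(vs[i], 4994, opt)
    m <- extract_particles(blur, opt)
    raw[i] <- m$area_px
    lift[i] <- corrected_area(blur, spec, opt)$area_px
    comp[i] <- sum(restore_compress(blur, spec, m$y_extent_px) > 0)
  }
  expect_true(all(diff(raw) > 0))
  expect_lte(diff(range(lift)) / mean(lift), 0.03)
  expect_gt(stats::var(comp), stats::var(lift))
})
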