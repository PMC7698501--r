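test_that("a stationary particle renders as a symmetric disk", {
  sp <- particle_spec(28, 15, diameter_um = 12, velocity_mps = 0)
  img <- render_blurred_particle(sp, 4994, opt_default, c(50, 80))
  m <- extract_particles(binarize(img, 0), opt_default)
  expect_equal(nrow(m), 1)
  expect_equal(m$x_extent_px, m$y_extent_px)
  # interior pixels are covered the whole exposure
  expect_equal(max(img), 200)
})

test_that("streak support is the disk swept by v * t (support algebra)", {
  # 21-px disk moving 5 px during the long exposure -> 26-px support
  d <- diameter_for_px(21)
  v <- velocity_for_px(5, 4994)
  sp <- particle_spec(28, 10, d, v)
  img <- render_blurred_particle(sp, 4994, opt_default, c(60, 80))
  m <- extract_particles(binarize(img, 0), opt_default)
  expect_equal(m$y_extent_px, 26)
  expect_equal(m$x_extent_px, 21)

  # property: Y-extent(v, t) - Y-extent(0) = round(v t / p) +- 1 px
  # over a grid of velocities and both exposures
  stat <- extract_particles(
    binarize(render_blurred_particle(particle_spec(28, 10, d, 0),
                                     4994, opt_default, c(60, 80)), 0),
    opt_default)$y_extent_px
  for (v_mm in c(0.4, 0.9, 1.7, 2.6)) {
    for (t_us in c(2500, 4994)) {
      vv <- v_mm * 1e-3
      rows <- ceiling((10 + d / 2 + vv * t_us + 5) / 0.704)
      img <- render_blurred_particle(particle_spec(28, 10, d, vv),
                                     t_us, opt_default, c(rows, 80))
      yext <- extract_particles(binarize(img, 0), opt_default)$y_extent_px
      expected <- round(vv * t_us / 0.704)
      expect_lte(abs((yext - stat) - expected), 1)
    }
  }
})

test_that("worked-example pair differs by 5 px between the exposures", {
  v <- 1.41e-3
  pair <- render_pair(v, diameter_um = diameter_for_px(21))
  mL <- extract_particles(binarize(pair$long, 0), opt_default)
  mS <- extract_particles(binarize(pair$short, 0), opt_default)
  expect_equal(mL$y_extent_px - mS$y_extent_px,
               round(1.41e-3 * 2494e-6 / 0.704e-6))  # 5 px
})

test_that("analytic renderer matches the temporal-supersampling oracle", {
  for (v_mm in c(0, 0.7, 1.9)) {
    for (t_us in c(2500, 4994)) {
      sp <- particle_spec(17.3, 9.1, 12.4, v_mm * 1e-3)
      rows <- ceiling((9.1 + 6.2 + v_mm * 1e-3 * t_us * 1e3 + 4) / 0.704)
      a <- render_blurred_particle(sp, t_us, opt_default, c(rows, 50))
      o <- render_blurred_particle_oracle(sp, t_us, opt_default,
                                          c(rows, 50), n_steps = 400)
      expect_lte(max(abs(a - o)), 1)
    }
  }
})

test_that("blur redistributes signal without creating it (flux)", {
  # total integrated intensity equals intensity * disk area / pixel
  # area at every velocity; quantization and the start-phase
  # rasterization of the disk perturb it by well under 2%
  d <- 12
  flux <- 200 * pi * (d / 2)^2 / 0.704^2
  for (v_mm in c(0, 0.5, 1.4, 2.8)) {
    img <- render_blurred_particle(particle_spec(28, 12, d, v_mm * 1e-3),
                                   4994, opt_default, c(70, 80))
    expect_lt(abs(sum(img) - flux) / flux, 0.02)
  }
})

test_that("renderer refuses particles that exit the field", {
  sp <- particle_spec(28, 30, 12, 3e-3)  # streak ~15 um, field 35 um
  expect_error(render_blurred_particle(sp, 4994, opt_default, c(50, 80)),
               "overrun")
})

test_that("dual-channel renders are nested along the flow axis", {
  sc <- flow_scene(particle_spec(30, 12, 12, 1.7e-3),
                   channel_width_um = 60, field_length_um = 60)
  ch <- render_dual_channel(sc, opt_default)
  sup_long <- ch$long > 0
  sup_short <- ch$short > 0
  # long-exposure support strictly contains the short-exposure support
  expect_true(all(sup_long[sup_short]))
  expect_gt(sum(sup_long), sum(sup_short))

  # stationary particle: identical support in both channels
  sc0 <- flow_scene(particle_spec(30, 12, 12, 0),
                    channel_width_um = 60, field_length_um = 30)
  ch0 <- render_dual_channel(sc0, opt_default)
  expect_identical(ch0$long > 0, ch0$short > 0)

  # empty scene: two background-only images
  che <- render_dual_channel(flow_scene(list(), channel_width_um = 40,
                                        field_length_um = 30,
                                        background_level = 7),
                             opt_default)
  expect_true(all(che$long == 7) && all(che$short == 7))
})

test_that("channel noise is seeded and independent per channel", {
  sc <- flow_scene(list(), channel_width_um = 30, field_length_um = 30,
                   background_level = 100, noise_sigma = 5, rng_seed = 11)
  a <- render_dual_channel(sc, opt_default)
  b <- render_dual_channel(sc, opt_default)
  expect_identical(a, b)                    # reproducible
  expect_false(identical(a$long, a$short))  # independent draws
})

test_that("laminar profile is parabolic with no-slip walls", {
  w <- 73.9; vmax <- 2e-3
  expect_equal(laminar_velocity(w / 2, w, vmax), vmax)
  expect_equal(laminar_velocity(0, w, vmax), 0)
  expect_equal(laminar_velocity(w, w, vmax), 0)
  expect_equal(laminar_velocity(w / 4, w, vmax), 0.75 * vmax)
  expect_error(laminar_velocity(-1, w, vmax), "outside")
})
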