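test_that("default LED array reproduces the data-sheet table row for row", {
  arr <- led_array_default()
  expect_length(arr, 18L)
  expect_identical(band_wavelengths(arr),
                   c(405, 420, 450, 470, 505, 525, 555, 590, 610,
                     630, 660, 700, 770, 800, 830, 850, 890, 910))
  expect_identical(vapply(arr$channels, `[[`, numeric(1), "half_width"),
                   c(19, 16, 20, 25, 30, 30, 25, 13, 15,
                     15, 18, 21, 26, 29, 35, 40, 75, 47))
  expect_identical(vapply(arr$channels, `[[`, numeric(1), "viewing_angle"),
                   c(102, 26, 40, 80, 86, 18, 40, 64, 30,
                     60, 80, 80, 14, 88, 14, 26, 40, 30))
})

test_that("the packaged YAML config reproduces the default instrument", {
  inst <- load_instrument_config()
  expect_identical(band_wavelengths(inst$led_array),
                   band_wavelengths(led_array_default()))
  expect_identical(vapply(inst$led_array$channels, `[[`, numeric(1),
                          "viewing_angle"),
                   vapply(led_array_default()$channels, `[[`, numeric(1),
                          "viewing_angle"))
  expect_identical(c(inst$camera$rows, inst$camera$cols), c(720L, 1280L))
  expect_equal(inst$camera$fps_max, 120)
  expect_equal(inst$camera$angular_fov, 90)
})

test_that("emission profile is a unit-peak Gaussian with the stated FWHM", {
  cases <- list(c(405, 19), c(890, 75), c(610, 15))
  for (cs in cases) {
    ch <- led_channel(cs[1], cs[2], 40)
    expect_equal(emission_profile(ch, cs[1]), 1.0)
    expect_equal(emission_profile(ch, cs[1] + c(-1, 1) * cs[2] / 2),
                 c(0.5, 0.5))
  }
  # data-sheet row 890/75: half maximum at 852.5 nm
  expect_equal(emission_profile(led_channel(890, 75, 40), 852.5), 0.5)
  expect_error(emission_profile(led_channel(405, 19, 40), numeric(0)),
               "empty")
  expect_error(emission_profile(led_channel(405, 19, 40), c(500, 400)),
               "increasing")
})

test_that("emission profile integrates to the Gaussian closed form", {
  grid <- seq(380, 1000, by = 1)
  for (hw in c(13, 30, 75)) {
    ch <- led_channel(660, hw, 40)
    e <- emission_profile(ch, grid)
    integral <- sum((e[-1] + e[-length(e)]) / 2)  # trapezoid, 1 nm
    expect_equal(integral, hw * sqrt(pi / (4 * log(2))), tolerance = 0.01)
  }
})

test_that("illumination footprint follows 2 d tan(angle/2) and peaks at relative_power", {
  expect_equal(footprint_fwhm(led_channel(660, 18, 120),
                              geometry_config(10)), 34.64, tolerance = 1e-3)
  expect_equal(footprint_fwhm(led_channel(770, 26, 14),
                              geometry_config(70)), 17.19, tolerance = 1e-3)
  ch <- led_channel(660, 18, 60, position = c(3, -2), relative_power = 0.7)
  grid <- list(x = matrix(3, 1, 1), y = matrix(-2, 1, 1))
  expect_equal(illumination_field(ch, geometry_config(50), grid)[1, 1], 0.7)
  expect_error(illumination_field(led_channel(660, 18, 179.99, ),
                                  geometry_config(50), grid), NA)
  bad <- led_channel(660, 18, 100)
  bad$viewing_angle <- 185  # bypass constructor to hit the operation's guard
  expect_error(illumination_field(bad, geometry_config(50), grid), "180")
  # narrower viewing angle concentrates light: stronger corner falloff
  cam <- small_camera(); geo <- geometry_config(70)
  g <- pixel_grid(cam, geo)
  wide <- illumination_field(led_channel(660, 18, 102), geo, g)
  narrow <- illumination_field(led_channel(660, 18, 14), geo, g)
  expect_lt(narrow[1, 1] / max(narrow), wide[1, 1] / max(wide))
})

test_that("hypercube rate reproduces the prototype and real-time operating points", {
  expect_equal(hypercube_rate(120, 18, timing_config(1, 1)), 10 / 3)
  expect_equal(round(hypercube_rate(120, 18, timing_config(1, 1)), 1), 3.3)
  expect_equal(hypercube_rate(600, 30, timing_config(1, 0)), 20)
  expect_equal(hypercube_rate(77, 1, timing_config(1, 0)), 77)
  expect_error(hypercube_rate(0, 18), "fps")
})

test_that("hypercube rate is monotone and inverts through required_fps", {
  fps <- c(30, 120, 600); lambdas <- c(1, 18, 30)
  timings <- list(timing_config(1, 0), timing_config(1, 1), timing_config(2, 3))
  for (f in fps) for (tm in timings) {
    rates <- vapply(lambdas, function(l) hypercube_rate(f, l, tm), numeric(1))
    expect_true(all(diff(rates) < 0))
    for (l in lambdas)
      expect_equal(required_fps(l, hypercube_rate(f, l, tm), tm), f)
  }
  # more delay, slower cubes; more fps, faster cubes
  expect_lt(hypercube_rate(120, 18, timing_config(1, 2)),
            hypercube_rate(120, 18, timing_config(1, 1)))
  expect_gt(hypercube_rate(240, 18, timing_config(1, 1)),
            hypercube_rate(120, 18, timing_config(1, 1)))
  expect_equal(required_fps(30, 20, timing_config(1, 0)), 600)
  expect_equal(required_fps(18, 10 / 3, timing_config(1, 1)), 120)
  expect_equal(required_fps(1, 1, timing_config(1, 0)), 1)
  expect_error(required_fps(0, 10), "n_channels")
})

test_that("link throughput matches the 400 Mbps example and scales inversely", {
  tr <- transfer_rate(link_config(400, "binary"), 256, 256, 30, 10)
  expect_equal(tr$hps, 400 * 2^20 / (256 * 256 * 30 * 10))
  expect_equal(tr$hps, 21.33, tolerance = 1e-3)
  expect_identical(tr$hps_floor, 21)
  expect_equal(transfer_rate(link_config(400, "decimal"),
                             256, 256, 30, 10)$hps,
               4e8 / 19660800, tolerance = 1e-7)
  # exactly one cube of bits per second -> 1 hps
  one <- link_config(256 * 256 * 30 * 10 / 2^20, "binary")
  expect_equal(transfer_rate(one, 256, 256, 30, 10)$hps, 1)
  base <- transfer_rate(link_config(400), 128, 128, 16, 8)$hps
  expect_equal(transfer_rate(link_config(400), 256, 128, 16, 8)$hps, base / 2)
  expect_equal(transfer_rate(link_config(400), 128, 256, 16, 8)$hps, base / 2)
  expect_equal(transfer_rate(link_config(400), 128, 128, 32, 8)$hps, base / 2)
  expect_equal(transfer_rate(link_config(400), 128, 128, 16, 16)$hps, base / 2)
})

test_that("pixel pitch and field of view reproduce both systems' geometry", {
  expect_equal(round(pixel_pitch(91, 1280)), 71)
  expect_equal(round(pixel_pitch(102, 2048)), 50)
  expect_equal(pixel_pitch(1, 1000), 1)
  expect_equal(fov_extent(90, 10, c(1, 1))$diagonal, 20)
  expect_equal(fov_extent(60, 10)$diagonal, 11.55, tolerance = 1e-3)
  # 16:9 sensor, diagonal FOV 90 deg, distance chosen so the width is 91 mm
  d <- 91 * sqrt(16^2 + 9^2) / 16 / 2  # diagonal / 2 at tan(45) = 1
  fe <- fov_extent(90, d, c(16, 9))
  expect_equal(fe$width, 91, tolerance = 1e-6)
  expect_equal(fe$height, 91 * 9 / 16, tolerance = 1e-6)
  expect_equal(fe$height, 51, tolerance = 0.01)
  expect_error(fov_extent(180, 10), "angular_fov")
})

test_that("constructors enforce their invariants", {
  expect_error(led_channel(300, 19, 40), "center_wavelength")
  expect_error(led_channel(405, -1, 40), "half_width")
  expect_error(led_channel(405, 19, 200), "viewing_angle")
  expect_error(led_array(list(led_channel(500, 20, 40),
                              led_channel(450, 20, 40))), "increasing")
  expect_error(camera_model(bit_depth = 9), "bit_depth")
  expect_error(timing_config(0, 0), "pw_frames")
  expect_error(link_config(-1), "rate_value")
  expect_error(geometry_config(0), "working_distance")
})
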