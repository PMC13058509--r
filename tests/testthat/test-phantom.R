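# Phantom construction, shear-wave propagation and RF simulation physics.

test_that("phantom construction validates fields and derives the SCD", {
  ph <- make_phantom(thickness_mm = c(skin = 2, subcutaneous = 21, liver = 120))
  expect_equal(ph$scd_mm, 23)
  expect_true(all(diff(ph$boundaries_mm) > 0))

  ph17 <- make_phantom(scd_mm = 17)
  expect_equal(ph17$scd_mm, 17)

  expect_error(make_phantom(youngs_modulus_kpa = c(skin = 30, subcutaneous = 10,
                                                   liver = 500)),
               "youngs_modulus_kpa")
  expect_error(make_phantom(atten_db_cm_mhz = c(skin = 1, subcutaneous = 0.6,
                                                liver = 3)),
               "atten_db_cm_mhz")
  # stress phantoms beyond the physiologic attenuation range are allowed
  # only explicitly
  expect_silent(make_phantom(liver_atten = 3, strict = FALSE))
  expect_error(make_phantom(vessels = data.frame(lateral_mm = 0, depth_mm = 10,
                                                 radius_mm = 2)),
               "liver")
})

test_that("homogeneous liver-only phantom labels are all liver", {
  ph <- liver_only_phantom()
  lab <- phantom_labels(ph, seq(5, 100, by = 1), seq(-30, 30, by = 1))
  expect_true(all(lab))
})

test_that("the two acquisition modes carry the device parameter quadruples", {
  std <- acquisition_mode("standard")
  enh <- acquisition_mode("enhanced")
  expect_equal(c(std$image_depth_mm, std$gain_db, std$vibration_pp_mm),
               c(140, 50, 2))
  expect_equal(std$meas_range_mm, c(25, 65))
  expect_equal(c(enh$image_depth_mm, enh$gain_db, enh$vibration_pp_mm),
               c(180, 70, 3))
  expect_equal(enh$meas_range_mm, c(35, 75))
  # measurement range sits inside the imaging depth
  expect_lt(enh$meas_range_mm[2], enh$image_depth_mm)
})

test_that("shear speed follows E = 3 rho c_s^2 exactly", {
  ph3 <- liver_only_phantom(kpa = 3)
  expect_equal(shear_speed_layers(ph3)[3], 1.0, tolerance = 1e-12)
  ph144 <- liver_only_phantom(kpa = 14.4)
  expect_equal(shear_speed_layers(ph144)[3], sqrt(14.4e3 / 3e3),
               tolerance = 1e-12)
  expect_equal(shear_speed_layers(ph144)[3], 2.191, tolerance = 1e-3)
})

test_that("propagated wave is causal with the mode's surface amplitude", {
  ph <- liver_only_phantom(kpa = 6.75)   # c_s = 1.5 m/s
  mode <- acquisition_mode("standard")
  disp <- propagate_shear_wave(ph, mode, duration_ms = 60)
  tau <- shear_arrival_ms(ph, disp$depth_axis_mm)
  for (r in seq(1, length(disp$depth_axis_mm), by = 7)) {
    before <- disp$time_axis_ms < tau[r]
    expect_true(all(disp$u_um[r, before] == 0))
  }
  pp <- diff(range(disp$u_um[1, ]))
  expect_equal(pp, mode$vibration_pp_mm * 1000, tolerance = 1e-2)
})

test_that("doubling stiffness contracts arrival times by sqrt(2)", {
  ph1 <- liver_only_phantom(kpa = 8)
  ph2 <- liver_only_phantom(kpa = 16)
  z <- c(20, 40, 60)
  expect_equal(shear_arrival_ms(ph1, z) / shear_arrival_ms(ph2, z),
               rep(sqrt(2), 3), tolerance = 1e-12)
})

test_that("propagation rejects too-short windows and aliasing frame rates", {
  ph <- liver_only_phantom()
  expect_error(propagate_shear_wave(ph, duration_ms = 30), "two vibration periods")
  expect_error(propagate_shear_wave(ph, frame_rate_hz = 150), "alias")
})

test_that("RF simulation is deterministic and zero without scatterers", {
  ph <- make_phantom(scd_mm = 17, seed = 5)
  mode <- acquisition_mode("standard")
  rf1 <- simulate_rf(ph, mode, n_lines = 16, seed = 5, depth_mm = 50)
  rf2 <- simulate_rf(ph, mode, n_lines = 16, seed = 5, depth_mm = 50)
  expect_identical(rf1$samples, rf2$samples)
  rf3 <- simulate_rf(ph, mode, n_lines = 16, seed = 6, depth_mm = 50)
  expect_false(identical(rf1$samples, rf3$samples))

  rf0 <- simulate_rf(ph, mode, n_lines = 4, seed = 5, depth_mm = 50,
                     scatterers_per_mm = 0, interface_amp = 0)
  expect_true(all(rf0$samples == 0))
})

test_that("B-mode gain acts as a constant dB offset and shows the capsule", {
  ph <- make_phantom(scd_mm = 20, seed = 9)
  rf <- simulate_rf(ph, acquisition_mode("standard"), n_lines = 32, seed = 9,
                    depth_mm = 60, lateral_width_mm = 20)
  bm50 <- form_bmode(rf, gain_db = 50)
  bm70 <- form_bmode(rf, gain_db = 70)
  expect_equal(bm70$image_db - bm50$image_db,
               matrix(20, nrow(bm50$image_db), ncol(bm50$image_db)),
               tolerance = 1e-9)
  # brightest shallow intensity step at the capsule depth
  mid <- bm50$image_db[, 16]
  shallow <- bm50$depth_axis_mm > 5 & bm50$depth_axis_mm < 30
  pk <- bm50$depth_axis_mm[shallow][which.max(mid[shallow])]
  expect_lt(abs(pk - 20), 0.5)

  rf0 <- simulate_rf(ph, acquisition_mode("standard"), n_lines = 4, seed = 5,
                     depth_mm = 50, scatterers_per_mm = 0, interface_amp = 0)
  bm0 <- form_bmode(rf0)
  expect_lt(diff(range(bm0$image_db)), 1e-6)  # uniform floor
})

test_that("spectral decay of simulated RF matches the configured attenuation", {
  profile_slope_at <- function(alpha, f_target_mhz = 3.5) {
    ph <- liver_only_phantom(alpha = alpha, seed = 13)
    rf <- simulate_rf(ph, acquisition_mode("standard"), n_lines = 128,
                      seed = 13, depth_mm = 110, interface_amp = 0)
    sp <- compute_spectra(rf)
    j <- which.min(abs(sp$freq_axis_hz / 1e6 - f_target_mhz))
    unname(coef(lm(sp$power_db[, j] ~ I(sp$depth_axis_mm / 10)))[2])
  }
  s05 <- profile_slope_at(0.5)
  s10 <- profile_slope_at(1.0)
  # analytic filter: power dB falls at 2 alpha f per cm (round-trip intensity)
  expect_equal(s05, -2 * 0.5 * 3.5, tolerance = 0.05 * abs(2 * 0.5 * 3.5))
  expect_equal(s10, -2 * 1.0 * 3.5, tolerance = 0.05 * abs(2 * 1.0 * 3.5))
  expect_equal(s10 / s05, 2, tolerance = 0.1)
})

test_that("RF series round-trips through the binary + JSON container", {
  ph <- make_phantom(scd_mm = 17, seed = 3)
  rf <- simulate_rf(ph, acquisition_mode("standard"), n_lines = 8, seed = 3,
                    depth_mm = 40)
  path <- file.path(tempdir(), "rf_roundtrip")
  write_rf_series(rf, path)
  back <- read_rf_series(path)
  expect_equal(back$samples, rf$samples)
  expect_equal(back$depth_axis_mm, rf$depth_axis_mm)
  expect_equal(back$mode$name, rf$mode$name)
  unlink(paste0(path, c(".bin", ".json")))
})

test_that("phantom configs round-trip through YAML", {
  ph <- make_phantom(scd_mm = 21, liver_kpa = 9,
                     vessels = data.frame(lateral_mm = 5, depth_mm = 60,
                                          radius_mm = 4),
                     seed = 77)
  path <- file.path(tempdir(), "phantom.yaml")
  write_phantom_config(ph, path)
  back <- read_phantom_config(path)
  expect_equal(back$layers, ph$layers)
  expect_equal(back$scd_mm, ph$scd_mm)
  expect_equal(back$vessels$radius_mm, 4)
  unlink(path)
})
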