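# Parenchyma masking, the >80% qualification rule, spectral profiles,
# reference-phantom attenuation estimation, calibration and the MAP clamp.

test_that("mask qualification is strict at 0.80", {
  expect_false(qualify_mask(0.80))
  expect_true(qualify_mask(0.801))
  expect_false(qualify_mask(parenchyma_mask(0.7)))
  # fine sweep locates the switch point exactly at 80%
  grid <- seq(0.70, 0.90, by = 0.001)
  q <- vapply(grid, qualify_mask, logical(1))
  expect_equal(max(grid[!q]), 0.80, tolerance = 1e-9)
  expect_equal(min(grid[q]), 0.801, tolerance = 1e-9)
})

test_that("segmentation scores vessel load against ground truth", {
  mode <- acquisition_mode("standard")
  clean <- make_phantom(scd_mm = 15, seed = 61)
  rf <- simulate_rf(clean, mode, n_lines = 128, seed = 61, depth_mm = 110)
  m0 <- segment_parenchyma(form_bmode(rf), phantom = clean)
  expect_gt(m0$liver_fraction, 0.98)
  expect_true(m0$qualified)

  # vessels covering >= 25% of the candidate parenchyma region
  big <- make_phantom(
    scd_mm = 15, seed = 61,
    vessels = data.frame(lateral_mm = c(-20, 0, 20, -10, 10),
                         depth_mm = c(40, 60, 45, 80, 85),
                         radius_mm = c(12, 12, 12, 11, 11)))
  rfb <- simulate_rf(big, mode, n_lines = 128, seed = 61, depth_mm = 110)
  bm <- form_bmode(rfb)
  lab <- phantom_labels(big, bm$depth_axis_mm, bm$lateral_axis_mm)
  region <- bm$depth_axis_mm > 16 & bm$depth_axis_mm >= 20 & bm$depth_axis_mm < 100
  coverage <- 1 - mean(lab[region, ])
  expect_gte(coverage, 0.25)
  mb <- segment_parenchyma(bm, phantom = big)
  expect_lte(mb$liver_fraction, 0.75)
  expect_false(mb$qualified)

  # ~10% vessel load stays qualified
  small <- make_phantom(
    scd_mm = 15, seed = 61,
    vessels = data.frame(lateral_mm = c(-15, 15), depth_mm = c(50, 75),
                         radius_mm = c(9, 9)))
  rfs <- simulate_rf(small, mode, n_lines = 128, seed = 61, depth_mm = 110)
  ms <- segment_parenchyma(form_bmode(rfs), phantom = small)
  expect_gt(ms$liver_fraction, 0.80)
  expect_true(ms$qualified)
})

test_that("a B-mode without any capsule yields an empty unqualified mask", {
  ph <- liver_only_phantom(seed = 63)
  rf <- simulate_rf(ph, acquisition_mode("standard"), n_lines = 32, seed = 63,
                    depth_mm = 110, interface_amp = 0)
  m <- segment_parenchyma(form_bmode(rf), phantom = ph)
  expect_false(m$qualified)
  expect_equal(m$liver_fraction, 0)
})

test_that("256 lines in blocks of 32 give exactly 8 averaged blocks", {
  ph <- liver_only_phantom(seed = 65)
  rf <- simulate_rf(ph, acquisition_mode("standard"), n_lines = 256, seed = 65,
                    depth_mm = 110, interface_amp = 0)
  sp <- compute_spectra(rf, block_size = 32)
  expect_equal(sp$n_blocks, 8)
  expect_true(all(sp$depth_axis_mm >= 20 & sp$depth_axis_mm < 100))
  expect_true(all(is.finite(sp$power_db)))
})

test_that("white-noise RF has a depth-flat spectral profile", {
  ph <- liver_only_phantom(seed = 67)
  rf <- simulate_rf(ph, acquisition_mode("standard"), n_lines = 64, seed = 67,
                    depth_mm = 110, scatterers_per_mm = 0, interface_amp = 0)
  set.seed(67)
  rf$samples[] <- rnorm(length(rf$samples))
  sp <- compute_spectra(rf)
  depth_cm <- sp$depth_axis_mm / 10
  band <- which(sp$freq_axis_hz > 1e6 & sp$freq_axis_hz < 8e6)
  slopes <- vapply(band, function(j) {
    unname(coef(lm(sp$power_db[, j] ~ depth_cm))[2])
  }, numeric(1))
  expect_lt(max(abs(slopes)), 0.5)    # dB/cm against 3.5 dB/cm for liver
})

test_that("raw attenuation is zero against itself and antisymmetric", {
  ph <- liver_only_phantom(alpha = 0.75, seed = 69)
  rf <- simulate_rf(ph, acquisition_mode("standard"), n_lines = 128, seed = 69,
                    depth_mm = 110, interface_amp = 0)
  sp <- compute_spectra(rf)
  expect_equal(estimate_raw_attenuation(sp, sp)$raw_slope_db_cm_mhz, 0,
               tolerance = 1e-12)

  ph2 <- liver_only_phantom(alpha = 0.5, seed = 70)
  rf2 <- simulate_rf(ph2, acquisition_mode("standard"), n_lines = 128,
                     seed = 70, depth_mm = 110, interface_amp = 0)
  sp2 <- compute_spectra(rf2)
  ab <- estimate_raw_attenuation(sp, sp2)$raw_slope_db_cm_mhz
  ba <- estimate_raw_attenuation(sp2, sp)$raw_slope_db_cm_mhz
  expect_equal(ab, -ba, tolerance = 1e-9)
  expect_lt(abs(ab - 0.25), 0.05)
})

test_that("calibration fits exactly on collinear points and predicts anchors", {
  cal <- fit_calibration(known_db_m = c(175, 350), raw_slope = c(0, 0.5))
  expect_equal(cal$points$residual, c(0, 0), tolerance = 1e-10)
  expect_equal(cal$intercept, 175)        # reference's own raw slope is 0
  expect_equal(cal$slope, 350)
  expect_error(fit_calibration(c(175, 175), c(0, 0.2)), "distinct")
  expect_error(fit_calibration(175, 0), "equal length|distinct")
})

test_that("reference-phantom pipeline recovers alpha0 x 350 within 15 dB/m", {
  cal <- shared_calibration()
  known <- c(0.5, 1.0) * 350
  expect_true(all(abs(cal$points$known_db_m - known) < 1e-9))
  expect_lt(sqrt(mean(cal$points$residual^2)), 1)
  # held-out phantom between the anchors
  ph <- liver_only_phantom(alpha = 0.75, seed = 71)
  rf <- simulate_rf(ph, acquisition_mode("standard"), n_lines = 256, seed = 71,
                    depth_mm = 110, interface_amp = 0)
  sp <- compute_spectra(rf)
  raw <- estimate_raw_attenuation(sp, cal$reference_profile)
  mp <- map_value(raw, cal)
  expect_lt(abs(mp$map_db_m - 0.75 * 350), 15)
})

test_that("MAP output clamps to [100, 400] dB/m", {
  cal <- fit_calibration(known_db_m = c(175, 350), raw_slope = c(0, 0.5))
  expect_equal(map_value(0.2143, cal)$map_db_m, 175 + 350 * 0.2143)  # interior
  expect_equal(map_value(20, cal)$map_db_m, 400)    # absurd high -> clamp
  expect_equal(map_value(-5, cal)$map_db_m, 100)    # absurd low -> clamp
  msk <- parenchyma_mask(0.5)
  res <- map_value(0.2, cal, mask = msk)
  expect_false(res$valid)                 # value reported but flagged
  expect_true(is.finite(res$map_db_m))
})

test_that("MAP is invariant to overall gain scaling of the RF", {
  cal <- shared_calibration()
  ph <- make_phantom(scd_mm = 15, liver_atten = 0.6, seed = 73)
  rf <- simulate_rf(ph, acquisition_mode("standard"), n_lines = 256, seed = 73,
                    depth_mm = 110)
  m1 <- estimate_map(rf, cal, phantom = ph)
  rf$samples <- rf$samples * 7.3
  m2 <- estimate_map(rf, cal, phantom = ph)
  expect_equal(m1$map_db_m, m2$map_db_m, tolerance = 1e-6)
})

test_that("MAP rises monotonically with true attenuation", {
  cal <- shared_calibration()
  alphas <- c(0.3, 0.5, 0.75, 1.0)
  maps <- vapply(alphas, function(a) {
    ph <- make_phantom(scd_mm = 15, liver_atten = a, seed = 75)
    rf <- simulate_rf(ph, acquisition_mode("standard"), n_lines = 256,
                      seed = 75, depth_mm = 110)
    estimate_map(rf, cal, phantom = ph)$map_db_m
  }, numeric(1))
  expect_true(all(diff(maps) > 0))
  expect_true(all(abs(maps - alphas * 350) < 15))
})

test_that("calibration models round-trip through JSON", {
  cal <- shared_calibration()
  path <- file.path(tempdir(), "cal.json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(back$slope, cal$slope, tolerance = 1e-9)
  expect_equal(back$intercept, cal$intercept, tolerance = 1e-9)
  expect_equal(back$reference_profile$power_db, cal$reference_profile$power_db,
               tolerance = 1e-9, ignore_attr = TRUE)
  unlink(path)
})
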