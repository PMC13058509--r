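# Displacement tracking, elastogram QC, trajectory detection and the
# modulus conversion.

test_that("a static phantom tracks to a near-zero elastogram", {
  ph <- make_phantom(scd_mm = 15, seed = 41)
  mode <- acquisition_mode("standard")
  still <- propagate_shear_wave(ph, mode, duration_ms = 40)
  still$u_um[] <- 0
  still$u_um <- still$u_um[, 1:5]
  still$time_axis_ms <- still$time_axis_ms[1:5]
  rf <- simulate_rf(ph, mode, displacement = still, n_lines = 1, seed = 41,
                    depth_mm = 70)
  e <- track_displacement(rf)
  # sub-sample interpolation noise only: a few um/ms against wave crests of
  # hundreds of um/ms
  expect_lt(max(abs(e$m)), 5)
  qc <- qc_elastogram(e)
  expect_false(qc$passed)
})

test_that("a rigid whole-frame shift is recovered within one RF sample", {
  ph <- make_phantom(scd_mm = 15, seed = 43)
  mode <- acquisition_mode("standard")
  shift <- propagate_shear_wave(ph, mode, duration_ms = 40)
  shift$u_um <- cbind(rep(0, nrow(shift$u_um)), rep(100, nrow(shift$u_um)))
  shift$time_axis_ms <- c(0, 0.5)
  rf <- simulate_rf(ph, mode, displacement = shift, n_lines = 1, seed = 43,
                    depth_mm = 70)
  e <- track_displacement(rf)
  disp_um <- e$m[, 1] * 0.5     # velocity x frame interval
  rf_sample_um <- 1540 / (2 * 20e6) * 1e6
  expect_lt(abs(median(disp_um) - 100), rf_sample_um)
})

test_that("a simulated 50-Hz wave leaves a ridge at the shear speed", {
  ph <- liver_only_phantom(kpa = 6.75, seed = 45)  # c_s = 1.5 mm/ms
  mode <- acquisition_mode("standard")
  disp <- propagate_shear_wave(ph, mode, duration_ms = 80)
  rf <- simulate_rf(ph, mode, displacement = disp, n_lines = 1, seed = 45,
                    depth_mm = 80)
  e <- track_displacement(rf)
  traj <- detect_trajectory(e)
  expect_equal(traj$slope_m_per_s, 1.5, tolerance = 0.1)
})

test_that("trajectory transform finds an exact synthetic line", {
  m <- matrix(0, 30, 40)
  m[cbind(1:30, 1:30)] <- 1          # dz 1 mm, dt 0.5 ms -> slope 2 mm/ms
  e <- synthetic_elastogram(m)
  traj <- detect_trajectory(e, onset_window_ms = 0)
  expect_equal(traj$slope_m_per_s, 2.0, tolerance = 0.02)
})

test_that("with two crossing lines the stronger one wins, matching brute force", {
  m <- matrix(0, 30, 60)
  m[cbind(1:30, 1:30)] <- 1.0                      # slope 2.0 mm/ms
  idx2 <- cbind(1:30, 25 + 2 * (1:30))             # slope 1.0 mm/ms
  idx2 <- idx2[idx2[, 2] <= 60, ]
  m[idx2] <- m[idx2] + 0.5
  e <- synthetic_elastogram(m)
  traj <- detect_trajectory(e, onset_window_ms = 0)
  oracle <- brute_force_line_slope(e)
  expect_equal(traj$slope_m_per_s, 2.0, tolerance = 0.05)
  expect_equal(traj$slope_m_per_s, oracle, tolerance = 0.05)
})

test_that("transform-peak slope agrees with exhaustive search on random lines", {
  set.seed(99)
  for (rep in 1:4) {
    true_slope <- runif(1, 0.8, 4)
    m <- matrix(rnorm(40 * 50, sd = 0.05), 40, 50)
    for (r in 1:40) {
      tt <- (r - 1) / true_slope          # mm over mm/ms -> ms
      ti <- round(tt / 0.5) + 1
      if (ti >= 1 && ti <= 50) m[r, ti] <- m[r, ti] + 1
    }
    e <- synthetic_elastogram(m)
    traj <- detect_trajectory(e, onset_window_ms = 0)
    oracle <- brute_force_line_slope(e)
    expect_equal(traj$slope_m_per_s, oracle, tolerance = 0.1 * oracle)
  }
})

test_that("a featureless noise map fails QC and yields no trajectory", {
  set.seed(7)
  m <- matrix(rnorm(40 * 60, sd = 0.5), 40, 60)
  e <- synthetic_elastogram(m)
  qc <- qc_elastogram(e)
  expect_false(qc$passed)
  expect_error(detect_trajectory(e), "no trajectory")
})

test_that("QC is deterministic and penalises a gap in the trajectory", {
  ph <- liver_only_phantom(kpa = 8, seed = 47)
  mode <- acquisition_mode("standard")
  disp <- propagate_shear_wave(ph, mode, duration_ms = 80)
  rf <- simulate_rf(ph, mode, displacement = disp, n_lines = 1, seed = 47,
                    depth_mm = 80)
  e <- track_displacement(rf)
  qc1 <- qc_elastogram(e)
  qc2 <- qc_elastogram(e)
  expect_identical(qc1$scores, qc2$scores)
  expect_true(qc1$passed)

  # zero out the middle third of the depth rows: continuity must collapse
  broken <- e
  third <- seq(floor(nrow(e$m) / 3), floor(2 * nrow(e$m) / 3))
  broken$m[third, ] <- 0
  qc3 <- qc_elastogram(broken)
  expect_lt(qc3$scores["continuity"], qc_thresholds()["continuity"])
  expect_false(qc3$passed)
})

test_that("slope converts to Young's modulus by E = 3 rho c^2", {
  expect_equal(stiffness_from_slope(1.0)$youngs_modulus_kpa, 3.0)
  expect_equal(stiffness_from_slope(2.191)$youngs_modulus_kpa, 14.40,
               tolerance = 1e-2)
  expect_equal(stiffness_from_slope(1.653)$youngs_modulus_kpa, 8.20,
               tolerance = 1e-2)
  expect_error(stiffness_from_slope(-1), "positive")
  # round trip with the propagation model
  ph <- liver_only_phantom(kpa = 12.3)
  cs <- shear_speed_layers(ph)[3]
  expect_equal(stiffness_from_slope(cs)$youngs_modulus_kpa, 12.3,
               tolerance = 1e-12)
})

test_that("a clean acquisition at the significant-fibrosis band recovers truth", {
  ph <- make_phantom(scd_mm = 17, liver_kpa = 8.2, seed = 49)
  st <- acquire_stiffness(ph, seed = 49)
  expect_true(st$valid)
  expect_equal(st$shear_speed_m_s, sqrt(8200 / 3000), tolerance = 0.1)
  expect_equal(st$youngs_modulus_kpa, 8.2, tolerance = 0.1 * 8.2)
})
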