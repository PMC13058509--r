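# Exam protocol: SCD measurement, automatic standard/enhanced mode selection,
# and the ten-valid-measurement acquisition loop with median reporting.

#' Measure the skin-to-liver-capsule distance (SCD)
#'
#' Locates interface echoes on the midline A-line of a B-mode image: the
#' envelope is smoothed, normalised by a rolling RMS, and the deepest
#' prominent peak within the plausible capsule range is taken as the liver
#' capsule. The SCD is its depth in mm from the transducer face.
#'
#' @param bmode a [form_bmode()] image.
#' @param search_range_mm depth range searched for the capsule.
#' @param prominence peak threshold on the locally normalised envelope.
#' @return SCD in mm.
#' @export
measure_scd <- function(bmode, search_range_mm = c(0.5, 45), prominence = 6) {
  mid <- ceiling(ncol(bmode$image_db) / 2)
  env <- 10^((bmode$image_db[, mid] - bmode$gain_db) / 20)
  z <- bmode$depth_axis_mm
  dz <- diff(z[1:2])
  k <- max(round(0.15 / dz), 1)
  env_s <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env_s[is.na(env_s)] <- env[is.na(env_s)]
  half <- max(round(2.5 / dz), 2)
  core <- max(round(0.6 / dz), 1)
  csum <- cumsum(c(0, env_s^2))
  n <- length(env_s)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  clo <- pmax(seq_len(n) - core, 1)
  chi <- pmin(seq_len(n) + core, n)
  # background RMS excludes the candidate echo itself, so a strong specular
  # peak is judged against the surrounding speckle only
  bg_ss <- (csum[hi + 1] - csum[lo]) - (csum[chi + 1] - csum[clo])
  bg_n <- (hi - lo + 1) - (chi - clo + 1)
  rms <- sqrt(pmax(bg_ss, 0) / pmax(bg_n, 1))
  ratio <- env_s / pmax(rms, .Machine$double.eps)
  in_range <- z >= search_range_mm[1] & z <= search_range_mm[2]
  locmax <- ratio >= c(-Inf, ratio[-n]) & ratio >= c(ratio[-1], -Inf)
  peaks <- which(in_range & locmax & ratio > prominence)
  if (!length(peaks)) abort("no capsule interface found on the midline A-line.")
  unname(z[max(peaks)])
}

#' Automatic acquisition-mode selection from the SCD
#'
#' The device defaults to the standard mode and activates the enhanced mode
#' (deeper imaging, higher gain, larger vibration, deeper measurement range)
#' when the skin-to-liver-capsule distance exceeds 20 mm. The boundary is
#' strict: an SCD of exactly 20 mm keeps the standard mode.
#'
#' @param scd_mm skin-to-liver-capsule distance, mm.
#' @return An [acquisition_mode()].
#' @export
#' @examples
#' select_mode(17)$name  # "standard"
#' select_mode(23)$name  # "enhanced"
select_mode <- function(scd_mm) {
  check_number(scd_mm, "scd_mm", len = 1)
  if (scd_mm < 0) abort("`scd_mm` must be non-negative.")
  acquisition_mode(if (scd_mm > 20) "enhanced" else "standard")
}

#' Single stiffness acquisition on a phantom
#'
#' One shear-wave shot: propagate the 50-Hz wave, acquire a single-line RF
#' frame series, and run the elastography chain. The speckle seed varies per
#' acquisition, which is what makes repeated measurements on the same
#' phantom scatter.
#'
#' @param phantom a [make_phantom()] object.
#' @param mode acquisition mode.
#' @param seed acquisition seed.
#' @param duration_ms slow-time extent of the shot.
#' @param depth_mm simulated depth (defaults to 15 mm past the measurement
#'   range).
#' @return A `pocte_stiffness` (possibly invalid).
#' @export
acquire_stiffness <- function(phantom, mode = acquisition_mode("standard"),
                              seed = 1, duration_ms = 80, depth_mm = NULL) {
  depth_mm <- depth_mm %||% (mode$meas_range_mm[2] + 15)
  disp <- propagate_shear_wave(phantom, mode, duration_ms = duration_ms)
  rf <- simulate_rf(phantom, mode, displacement = disp, n_lines = 1,
                    seed = seed, depth_mm = depth_mm)
  estimate_stiffness(rf)
}

#' Run a full simulated exam on a phantom
#'
#' Reproduces the examination protocol: a survey B-mode frame measures the
#' SCD and selects the acquisition mode once; acquisitions then repeat until
#' ten pass the elastogram quality control (or `max_attempts` is reached).
#' Each acquisition produces a stiffness result and, when a calibration is
#' supplied, a MAP result. The per-exam medians are taken over the first ten
#' valid acquisitions; an exam with fewer than ten valid measurements is
#' invalid (a measurement failure).
#'
#' @param phantom a [make_phantom()] object.
#' @param seed exam seed; acquisition seeds derive from it.
#' @param calibration optional [build_map_calibration()] model; without it
#'   MAP is skipped.
#' @param n_valid_target valid acquisitions required (10).
#' @param max_attempts acquisition cap.
#' @param mode optional forced mode (default: automatic from the SCD).
#' @return A `pocte_exam`: `scd_mm`, `mode`, `acquisitions` tibble,
#'   `lsm_median_kpa`, `map_median_db_m`, `lsm_iqr_over_median`,
#'   `map_iqr_over_median`, `n_valid`, `exam_valid`.
#' @export
run_exam <- function(phantom, seed = 1, calibration = NULL,
                     n_valid_target = 10, max_attempts = 20, mode = NULL) {
  survey_mode <- acquisition_mode("standard")
  rf_survey <- simulate_rf(phantom, survey_mode, n_lines = 64,
                           seed = seed, depth_mm = 60,
                           lateral_width_mm = 20)
  scd <- tryCatch(measure_scd(form_bmode(rf_survey)),
                  error = function(err) NA_real_)
  if (is.null(mode)) {
    mode <- if (is.na(scd)) survey_mode else select_mode(scd)
  }
  rows <- vector("list", max_attempts)
  n_valid <- 0L
  for (att in seq_len(max_attempts)) {
    att_seed <- seed * 1000L + att
    st <- acquire_stiffness(phantom, mode, seed = att_seed)
    mp <- NULL
    if (!is.null(calibration)) {
      rf_a <- simulate_rf(phantom, mode, n_lines = 256, seed = att_seed + 500L,
                          depth_mm = 110)
      mp <- tryCatch(estimate_map(rf_a, calibration, phantom = phantom),
                     error = function(err) NULL)
    }
    rows[[att]] <- tibble::tibble(
      attempt = att,
      shear_speed_m_s = st$shear_speed_m_s,
      lsm_kpa = st$youngs_modulus_kpa,
      qc_passed = isTRUE(st$valid),
      map_db_m = if (is.null(mp)) NA_real_ else mp$map_db_m,
      map_valid = if (is.null(mp)) NA else mp$valid
    )
    if (rows[[att]]$qc_passed) n_valid <- n_valid + 1L
    if (n_valid >= n_valid_target) break
  }
  acq <- dplyr::bind_rows(rows)
  valid_acq <- dplyr::filter(acq, .data$qc_passed)
  # the device stops at ten valid measurements; medians use the first ten
  used <- head(valid_acq, n_valid_target)
  lsm_med <- if (nrow(used)) median(used$lsm_kpa) else NA_real_
  lsm_iqr <- if (nrow(used) > 1) iqr_over_median(used$lsm_kpa) else NA_real_
  map_ok <- used$map_db_m[!is.na(used$map_db_m)]
  map_med <- if (length(map_ok)) median(map_ok) else NA_real_
  map_iqr <- if (length(map_ok) > 1) iqr_over_median(map_ok) else NA_real_
  structure(list(
    scd_mm = scd, mode = mode, acquisitions = acq,
    n_valid = nrow(valid_acq),
    lsm_median_kpa = lsm_med, map_median_db_m = map_med,
    lsm_iqr_over_median = lsm_iqr, map_iqr_over_median = map_iqr,
    exam_valid = nrow(valid_acq) >= n_valid_target,
    seed = seed
  ), class = "pocte_exam")
}

#' @export
print.pocte_exam <- function(x, ...) {
  cat(sprintf("<pocte_exam> SCD %.1f mm (%s mode), %d valid acquisitions -> %s\n",
              x$scd_mm, x$mode$name, x$n_valid,
              if (x$exam_valid) "valid exam" else "measurement failure"))
  if (x$exam_valid) {
    cat(sprintf("  USG-LSM %.2f kPa (IQR/median %.0f%%)", x$lsm_median_kpa,
                100 * x$lsm_iqr_over_median))
    if (!is.na(x$map_median_db_m)) {
      cat(sprintf(", MAP %.0f dB/m (IQR/median %.0f%%)", x$map_median_db_m,
                  100 * x$map_iqr_over_median))
    }
    cat("\n")
  }
  invisible(x)
}

#' Exam validity rule
#'
#' An examination is valid only when at least ten individual measurements
#' passed quality control.
#'
#' @param record a [run_exam()] result.
#' @param n_required minimum valid measurements.
#' @return `TRUE` or `FALSE`.
#' @export
exam_validity <- function(record, n_required = 10) {
  record$n_valid >= n_required
}

#' @method tidy pocte_exam
#' @export
tidy.pocte_exam <- function(x, ...) x$acquisitions

#' @method glance pocte_exam
#' @export
glance.pocte_exam <- function(x, ...) {
  tibble::tibble(
    scd_mm = x$scd_mm, mode = x$mode$name, n_valid = x$n_valid,
    exam_valid = x$exam_valid, lsm_median_kpa = x$lsm_median_kpa,
    map_median_db_m = x$map_median_db_m,
    lsm_iqr_over_median = x$lsm_iqr_over_median,
    map_iqr_over_median = x$map_iqr_over_median
  )
}
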