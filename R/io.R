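# Persistence: RF frame series as flat binary + JSON header, phantom and
# generator configs as YAML, calibration models and exam records as JSON,
# cohorts as CSV.

#' Write / read an RF frame series
#'
#' The series is stored as a flat little-endian float64 binary (`.bin`, the
#' sample array in line x depth x frame order) next to a JSON header
#' (`.json`) holding the axes, acquisition metadata and provenance; this is
#' the documented portable container for simulated RF.
#'
#' @param rf a [simulate_rf()] series.
#' @param path output path; `.bin` and `.json` extensions are appended.
#' @return `write_rf_series` the path, invisibly; `read_rf_series` a
#'   reconstructed `pocte_rf`.
#' @export
write_rf_series <- function(rf, path) {
  header <- list(
    format = "pocte-rf-1", dims = dim(rf$samples),
    n_lines = rf$n_lines, depth_axis_mm = rf$depth_axis_mm,
    lateral_axis_mm = rf$lateral_axis_mm,
    fs_hz = rf$fs_hz, frame_rate_hz = rf$frame_rate_hz,
    center_freq_hz = rf$center_freq_hz, mode = rf$mode$name,
    provenance = rf$provenance)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rf$samples), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_rf_series
#' @export
read_rf_series <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(header$format, "pocte-rf-1")) abort("not a pocte RF container.")
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(header$dims), size = 8,
                  endian = "little")
  structure(list(
    samples = array(vals, dim = header$dims), n_lines = header$n_lines,
    depth_axis_mm = header$depth_axis_mm,
    lateral_axis_mm = header$lateral_axis_mm, fs_hz = header$fs_hz,
    frame_rate_hz = header$frame_rate_hz,
    center_freq_hz = header$center_freq_hz,
    mode = acquisition_mode(header$mode), provenance = header$provenance
  ), class = "pocte_rf")
}

#' Write / read a phantom configuration
#'
#' Phantom configurations round-trip through YAML key-value files with the
#' same validation as [make_phantom()].
#'
#' @param phantom a [make_phantom()] object (or for reading, a path).
#' @param path file path.
#' @return The phantom (reading) or the path, invisibly (writing).
#' @export
write_phantom_config <- function(phantom, path) {
  cfg <- list(
    thickness_mm = as.list(setNames(phantom$layers$thickness_mm,
                                    phantom$layers$layer)),
    youngs_modulus_kpa = as.list(setNames(phantom$layers$youngs_modulus_kpa,
                                          phantom$layers$layer)),
    atten_db_cm_mhz = as.list(setNames(phantom$layers$atten_db_cm_mhz,
                                       phantom$layers$layer)),
    echogenicity = as.list(setNames(phantom$layers$echogenicity,
                                    phantom$layers$layer)),
    vessels = if (nrow(phantom$vessels)) as.list(phantom$vessels) else NULL,
    density_kg_m3 = phantom$density_kg_m3,
    seed = phantom$speckle_seed)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  make_phantom(
    thickness_mm = unlist(cfg$thickness_mm),
    youngs_modulus_kpa = unlist(cfg$youngs_modulus_kpa),
    atten_db_cm_mhz = unlist(cfg$atten_db_cm_mhz),
    echogenicity = if (!is.null(cfg$echogenicity)) unlist(cfg$echogenicity),
    vessels = if (!is.null(cfg$vessels)) tibble::as_tibble(cfg$vessels),
    density_kg_m3 = cfg$density_kg_m3 %||% 1000,
    seed = cfg$seed %||% 1L)
}

#' Serialize a calibration model to JSON
#'
#' @param calib a [fit_calibration()] / [build_map_calibration()] model.
#' @param path file path.
#' @return The path, invisibly. The reference spectral profile (if present)
#'   is embedded so the file is self-contained for [estimate_map()].
#' @export
write_calibration <- function(calib, path) {
  obj <- list(slope = calib$slope, intercept = calib$intercept,
              points = calib$points,
              center_freq_mhz = calib$center_freq_mhz)
  if (!is.null(calib$reference_profile)) {
    rp <- calib$reference_profile
    obj$reference_profile <- list(
      power_db = rp$power_db, depth_axis_mm = rp$depth_axis_mm,
      freq_axis_hz = rp$freq_axis_hz, n_lines_used = rp$n_lines_used,
      block_size = rp$block_size, n_blocks = rp$n_blocks)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calib <- structure(list(slope = obj$slope, intercept = obj$intercept,
                          points = tibble::as_tibble(obj$points),
                          center_freq_mhz = obj$center_freq_mhz),
                     class = "pocte_calibration")
  if (!is.null(obj$reference_profile)) {
    rp <- obj$reference_profile
    calib$reference_profile <- structure(
      list(power_db = as.matrix(rp$power_db),
           depth_axis_mm = rp$depth_axis_mm, freq_axis_hz = rp$freq_axis_hz,
           n_lines_used = rp$n_lines_used, block_size = rp$block_size,
           n_blocks = rp$n_blocks),
      class = "pocte_spectra")
  }
  calib
}

#' @method tidy pocte_calibration
#' @export
tidy.pocte_calibration <- function(x, ...) x$points

#' @method glance pocte_calibration
#' @export
glance.pocte_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 n_points = nrow(x$points),
                 rms_residual = sqrt(mean(x$points$residual^2)))
}

#' Write a cohort to CSV
#'
#' One row per patient; repetition columns keep their acquisition order.
#'
#' @param cohort a [synth_cohort()] tibble.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  df$fibrosis_stage <- factor(df$fibrosis_stage, levels = paste0("F", 0:4))
  df$steatosis_grade <- factor(df$steatosis_grade, levels = paste0("S", 0:3))
  class(df) <- c("pocte_cohort", class(df))
  df
}
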