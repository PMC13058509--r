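#' Acquisition modes of the point-of-care TE system
#'
#' The device operates in one of two fixed acquisition modes. The default
#' "standard" mode images to 140 mm at 50 dB gain with a 2 mm peak-to-peak
#' 50-Hz vibration and a 25-65 mm measurement range below the skin surface;
#' the "enhanced" mode (activated for deep-seated livers) images to 180 mm at
#' 70 dB with a 3 mm vibration and a 35-75 mm range.
#'
#' @param name `"standard"` or `"enhanced"`.
#' @return A `pocte_mode` list with fields `name`, `image_depth_mm`,
#'   `gain_db`, `vibration_pp_mm` and `meas_range_mm` (length-2 numeric).
#' @seealso [select_mode()] for the automatic SCD-driven choice.
#' @export
#' @examples
#' acquisition_mode("enhanced")$vibration_pp_mm
acquisition_mode <- function(name = c("standard", "enhanced")) {
  name <- match.arg(name)
  mode <- if (name == "standard") {
    list(name = "standard", image_depth_mm = 140, gain_db = 50,
         vibration_pp_mm = 2, meas_range_mm = c(25, 65))
  } else {
    list(name = "enhanced", image_depth_mm = 180, gain_db = 70,
         vibration_pp_mm = 3, meas_range_mm = c(35, 75))
  }
  structure(mode, class = "pocte_mode")
}

#' @export
print.pocte_mode <- function(x, ...) {
  cat(sprintf(
    "<pocte_mode> %s: depth %g mm, gain %g dB, vibration %g mm p-p, range %g-%g mm\n",
    x$name, x$image_depth_mm, x$gain_db, x$vibration_pp_mm,
    x$meas_range_mm[1], x$meas_range_mm[2]))
  invisible(x)
}

#' Construct a layered tissue phantom
#'
#' Builds the ground-truth medium used by every simulation in the package: a
#' stack of skin, subcutaneous and liver layers, each with its own Young's
#' modulus `E` (kPa) and frequency-linear attenuation coefficient
#' `alpha0` (dB/cm/MHz, intensity convention), optional anechoic vessel
#' disks inside the liver, and a speckle seed. The skin-to-liver-capsule
#' distance (SCD) equals the summed skin and subcutaneous thicknesses.
#'
#' @param thickness_mm named numeric: `skin`, `subcutaneous`, `liver`
#'   thicknesses in mm. Skin and subcutaneous layers may be 0 (a homogeneous
#'   liver-only phantom); the liver thickness must be positive.
#' @param youngs_modulus_kpa named numeric per layer, in kPa. Physiologic
#'   range 1-100 kPa.
#' @param atten_db_cm_mhz named numeric per layer, in dB/cm/MHz. Physiologic
#'   range 0-2.
#' @param echogenicity named numeric per layer, relative scatterer amplitude
#'   (liver = 1).
#' @param vessels data frame with columns `lateral_mm`, `depth_mm`,
#'   `radius_mm` describing circular vessel cross-sections; all disks must
#'   lie inside the liver layer.
#' @param density_kg_m3 tissue density; the TE convention fixes 1000.
#' @param seed speckle seed, an integer; drives scatterer placement in
#'   [simulate_rf()].
#' @param strict validate `E` and `alpha0` against the physiologic ranges
#'   above. `strict = FALSE` relaxes the attenuation ceiling to 5 dB/cm/MHz
#'   for deliberately non-physiologic stress phantoms (e.g. probing the
#'   output clamp of the attenuation estimator).
#' @return A `pocte_phantom` list; see Details for fields.
#' @details Fields: `layers` (tibble of per-layer properties),
#'   `boundaries_mm` (cumulative interface depths), `scd_mm`, `vessels`,
#'   `density_kg_m3`, `speckle_seed`, `total_depth_mm`.
#' @export
#' @examples
#' ph <- make_phantom(liver_kpa = 8.2)
#' ph$scd_mm
make_phantom <- function(thickness_mm = c(skin = 2, subcutaneous = 15, liver = 140),
                         youngs_modulus_kpa = c(skin = 30, subcutaneous = 10, liver = 6),
                         atten_db_cm_mhz = c(skin = 1.0, subcutaneous = 0.6, liver = 0.5),
                         echogenicity = c(skin = 1.5, subcutaneous = 0.8, liver = 1.0),
                         vessels = NULL, density_kg_m3 = 1000, seed = 1L,
                         strict = TRUE, liver_kpa = NULL, liver_atten = NULL,
                         scd_mm = NULL) {
  layer_names <- c("skin", "subcutaneous", "liver")
  take <- function(x, field, default) {
    if (is.null(names(x))) {
      if (length(x) != 3) abort(sprintf("`%s` must be named or length 3.", field))
      names(x) <- layer_names
    }
    out <- default
    out[names(x)] <- x
    out[layer_names]
  }
  thickness_mm <- take(thickness_mm, "thickness_mm",
                       c(skin = 2, subcutaneous = 15, liver = 140))
  # convenience scalar overrides used throughout the examples
  if (!is.null(scd_mm)) {
    check_number(scd_mm, "scd_mm", lo = 0)
    thickness_mm["subcutaneous"] <- max(scd_mm - thickness_mm["skin"], 0)
    if (scd_mm < thickness_mm["skin"]) thickness_mm["skin"] <- scd_mm
  }
  youngs_modulus_kpa <- take(youngs_modulus_kpa, "youngs_modulus_kpa",
                             c(skin = 30, subcutaneous = 10, liver = 6))
  atten_db_cm_mhz <- take(atten_db_cm_mhz, "atten_db_cm_mhz",
                          c(skin = 1.0, subcutaneous = 0.6, liver = 0.5))
  echogenicity <- take(echogenicity, "echogenicity",
                       c(skin = 1.5, subcutaneous = 0.8, liver = 1.0))
  if (!is.null(liver_kpa)) youngs_modulus_kpa["liver"] <- liver_kpa
  if (!is.null(liver_atten)) atten_db_cm_mhz["liver"] <- liver_atten

  check_number(thickness_mm, "thickness_mm", lo = 0, len = 3)
  if (thickness_mm["liver"] <= 0) abort("`thickness_mm` must give a positive liver thickness.")
  check_number(youngs_modulus_kpa, "youngs_modulus_kpa",
               lo = if (strict) 1 else 0.1, hi = if (strict) 100 else 500, len = 3)
  check_number(atten_db_cm_mhz, "atten_db_cm_mhz",
               lo = 0, hi = if (strict) 2 else 5, len = 3)
  check_number(echogenicity, "echogenicity", lo = 0, len = 3)
  check_number(density_kg_m3, "density_kg_m3", lo = 500, hi = 2000, len = 1)

  boundaries <- cumsum(thickness_mm)
  scd <- unname(boundaries["subcutaneous"])
  if (is.null(vessels)) {
    vessels <- tibble::tibble(lateral_mm = numeric(), depth_mm = numeric(),
                              radius_mm = numeric())
  } else {
    vessels <- tibble::as_tibble(vessels)
    need <- c("lateral_mm", "depth_mm", "radius_mm")
    if (!all(need %in% names(vessels))) {
      abort("`vessels` must have columns lateral_mm, depth_mm, radius_mm.")
    }
    check_number(vessels$radius_mm, "vessels$radius_mm", lo = 0)
    inside <- vessels$depth_mm - vessels$radius_mm >= scd &
      vessels$depth_mm + vessels$radius_mm <= boundaries["liver"]
    if (!all(inside)) abort("`vessels` must lie entirely within the liver layer.")
  }

  structure(list(
    layers = tibble::tibble(
      layer = layer_names,
      thickness_mm = unname(thickness_mm),
      youngs_modulus_kpa = unname(youngs_modulus_kpa),
      atten_db_cm_mhz = unname(atten_db_cm_mhz),
      echogenicity = unname(echogenicity)),
    boundaries_mm = unname(boundaries),
    scd_mm = scd,
    total_depth_mm = unname(boundaries["liver"]),
    vessels = vessels,
    density_kg_m3 = density_kg_m3,
    speckle_seed = as.integer(seed)
  ), class = "pocte_phantom")
}

#' @export
print.pocte_phantom <- function(x, ...) {
  cat(sprintf("<pocte_phantom> SCD %.1f mm, liver E %.1f kPa, alpha0 %.2f dB/cm/MHz, %d vessel(s)\n",
              x$scd_mm, x$layers$youngs_modulus_kpa[3],
              x$layers$atten_db_cm_mhz[3], nrow(x$vessels)))
  invisible(x)
}

# layer index (1 skin, 2 subcutaneous, 3 liver) at each depth; depths beyond
# the stack clamp to liver
layer_at_depth <- function(phantom, depth_mm) {
  fi <- findInterval(depth_mm, c(0, phantom$boundaries_mm[1:2]), left.open = TRUE)
  pmin(pmax(fi, 1L), 3L)
}

# per-layer shear speed, m/s (E = 3 rho c^2 with E in Pa)
shear_speed_layers <- function(phantom) {
  sqrt(phantom$layers$youngs_modulus_kpa * 1000 / (3 * phantom$density_kg_m3))
}

# one-way shear-wave arrival time (ms) at depths (mm): piecewise travel time
shear_arrival_ms <- function(phantom, depth_mm) {
  cs <- shear_speed_layers(phantom)        # m/s == mm/ms
  b <- c(0, phantom$boundaries_mm[1:2])
  t_at_b <- cumsum(c(0, diff(c(b, Inf))[1:2] / cs[1:2]))
  lay <- layer_at_depth(phantom, depth_mm)
  t_at_b[lay] + (depth_mm - b[lay]) / cs[lay]
}

# cumulative one-way attenuation (dB/MHz amplitude exponent base) at depths:
# sum over traversed layers of alpha0 * path_cm.  Used as amplitude factor
# 10^(-A(z) * f_MHz / 10), i.e. the intensity coefficient over a round trip.
cumulative_atten_db_mhz <- function(phantom, depth_mm) {
  a <- phantom$layers$atten_db_cm_mhz
  b <- c(0, phantom$boundaries_mm[1:2])
  A_at_b <- cumsum(c(0, diff(c(b, Inf))[1:2] / 10 * a[1:2]))
  lay <- layer_at_depth(phantom, depth_mm)
  A_at_b[lay] + (depth_mm - b[lay]) / 10 * a[lay]
}

# TRUE where (lateral, depth) falls inside a vessel disk
in_vessel <- function(phantom, lateral_mm, depth_mm) {
  out <- rep(FALSE, length(depth_mm))
  for (i in seq_len(nrow(phantom$vessels))) {
    v <- phantom$vessels[i, ]
    out <- out | ((lateral_mm - v$lateral_mm)^2 +
                    (depth_mm - v$depth_mm)^2 <= v$radius_mm^2)
  }
  out
}

#' Ground-truth tissue labels on an image grid
#'
#' Labels every pixel of a depth x lateral grid as liver parenchyma
#' (below the capsule and outside all vessel disks) or not, from the phantom
#' geometry. Used to score parenchyma masks against the known truth.
#'
#' @param phantom a [make_phantom()] object.
#' @param depth_axis_mm,lateral_axis_mm grid axes in mm.
#' @return Logical matrix, `length(depth_axis_mm)` x `length(lateral_axis_mm)`.
#' @export
phantom_labels <- function(phantom, depth_axis_mm, lateral_axis_mm) {
  out <- matrix(depth_axis_mm > phantom$scd_mm &
                  depth_axis_mm <= phantom$total_depth_mm,
                nrow = length(depth_axis_mm), ncol = length(lateral_axis_mm))
  for (i in seq_len(nrow(phantom$vessels))) {
    v <- phantom$vessels[i, ]
    dz2 <- (depth_axis_mm - v$depth_mm)^2
    dx2 <- (lateral_axis_mm - v$lateral_mm)^2
    out <- out & !(outer(dz2, dx2, `+`) <= v$radius_mm^2)
  }
  out
}
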