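# MAP chain: parenchyma masking with gradient denoising, the >80% mask
# qualification rule, block-averaged depth-resolved spectra, reference-phantom
# spectral-difference attenuation estimation, calibration, and the clamped
# MAP value in dB/m at 3.5 MHz.

#' Construct a parenchyma mask object
#'
#' Normally produced by [segment_parenchyma()]; the bare constructor exists so
#' that masks of controlled liver fraction can be built directly (e.g. for
#' sweeping the qualification rule).
#'
#' @param liver_fraction fraction of the mask area labelled liver tissue.
#' @param mask optional logical matrix (depth samples x lines).
#' @param depth_axis_mm,lateral_axis_mm optional grid axes.
#' @return A `pocte_mask` with `qualified = liver_fraction > 0.80`.
#' @export
parenchyma_mask <- function(liver_fraction, mask = NULL, depth_axis_mm = NULL,
                            lateral_axis_mm = NULL) {
  check_number(liver_fraction, "liver_fraction", lo = 0, hi = 1, len = 1)
  structure(list(mask = mask, liver_fraction = liver_fraction,
                 qualified = liver_fraction > 0.80,
                 depth_axis_mm = depth_axis_mm,
                 lateral_axis_mm = lateral_axis_mm),
            class = "pocte_mask")
}

#' @export
print.pocte_mask <- function(x, ...) {
  cat(sprintf("<pocte_mask> liver fraction %.3f -> %s\n", x$liver_fraction,
              if (x$qualified) "qualified" else "not qualified"))
  invisible(x)
}

#' Mask qualification rule
#'
#' A parenchyma mask qualifies for frequency-domain analysis only when liver
#' tissue constitutes strictly more than 80% of the mask area. The boundary
#' value 0.80 does not qualify.
#'
#' @param m a [parenchyma_mask()] / [segment_parenchyma()] object, or a bare
#'   liver fraction.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' qualify_mask(0.80)   # FALSE: strict inequality
#' qualify_mask(0.801)  # TRUE
qualify_mask <- function(m) {
  frac <- if (inherits(m, "pocte_mask")) m$liver_fraction else m
  check_number(frac, "liver_fraction", lo = 0, hi = 1, len = 1)
  frac > 0.80
}

#' Segment liver parenchyma on a B-mode image
#'
#' Boundary-threshold segmentation: the liver region is taken below the
#' deepest capsule interface (located as on [measure_scd()]), restricted to
#' the analysis depth range. A signal-gradient denoising step then excludes
#' pixels whose local axial intensity gradient magnitude exceeds the
#' configured percentile, removing heterogeneous signals such as vessel
#' boundaries and bright specular echoes from the samples passed to spectral
#' analysis.
#'
#' The mask-quality liver fraction is assessed on the candidate region
#' (below-capsule, in-range, before gradient exclusion): against the
#' ground-truth tissue labels when the phantom geometry is supplied, or by a
#' homogeneity self-classification (pixels within `homog_db` of the region
#' median intensity) otherwise. The returned `mask` has the gradient
#' exclusions applied.
#'
#' @param bmode a [form_bmode()] image.
#' @param phantom optional [make_phantom()] object providing ground truth.
#' @param depth_range_mm analysis depth range (half-open).
#' @param grad_quantile gradient-magnitude percentile above which pixels are
#'   excluded.
#' @param homog_db intensity half-width (dB) of the homogeneity
#'   classification used without ground truth.
#' @return A `pocte_mask`; `qualified` is `FALSE` with an empty mask when no
#'   capsule interface is found.
#' @export
segment_parenchyma <- function(bmode, phantom = NULL,
                               depth_range_mm = c(20, 100),
                               grad_quantile = 0.99, homog_db = 12) {
  capsule <- tryCatch(measure_scd(bmode), error = function(err) NA_real_)
  z <- bmode$depth_axis_mm
  nz <- length(z)
  nx <- ncol(bmode$image_db)
  if (is.na(capsule)) {
    return(parenchyma_mask(0, mask = matrix(FALSE, nz, nx),
                           depth_axis_mm = z,
                           lateral_axis_mm = bmode$lateral_axis_mm))
  }
  candidate <- matrix(z > capsule + 1 & z >= depth_range_mm[1] &
                        z < depth_range_mm[2], nz, nx)
  img <- bmode$image_db
  grad <- rbind(img[2, , drop = FALSE] - img[1, , drop = FALSE],
                (img[-(1:2), , drop = FALSE] - img[seq_len(nz - 2), , drop = FALSE]) / 2,
                img[nz, , drop = FALSE] - img[nz - 1, , drop = FALSE])
  g <- abs(grad)
  thr <- quantile(g[candidate], grad_quantile, names = FALSE)
  mask <- candidate & g <= thr
  if (!is.null(phantom)) {
    labels <- phantom_labels(phantom, z, bmode$lateral_axis_mm)
    frac <- mean(labels[candidate])
  } else {
    med <- median(img[mask])
    frac <- mean(abs(img[candidate] - med) <= homog_db)
  }
  out <- parenchyma_mask(frac, mask = mask, depth_axis_mm = z,
                         lateral_axis_mm = bmode$lateral_axis_mm)
  out
}

#' Depth-resolved block-averaged power spectra
#'
#' Computes the spectral profile feeding attenuation estimation: the 256 RF
#' lines are grouped into blocks (`block_size` = 32 giving 8 blocks), and for
#' each overlapping depth window in the 20-100 mm range a Welch-averaged
#' power spectrum of the Hann-gated RF is formed per block, restricted to
#' masked samples. A (block, window) cell is dropped when fewer than 50% of
#' its samples are masked; the profile is the block average in dB.
#'
#' @param rf a 256-line [simulate_rf()] series.
#' @param mask optional [segment_parenchyma()] mask (logical depth x lines);
#'   `NULL` uses all samples.
#' @param depth_range_mm analysed depth span, half-open.
#' @param block_size lines per averaging block.
#' @param window_mm depth gate length.
#' @param overlap window overlap fraction.
#' @param frame slow-time frame used.
#' @param nfft FFT length.
#' @return A `pocte_spectra`: `power_db` (depth windows x frequency bins),
#'   `depth_axis_mm` (window centres), `freq_axis_hz`, `n_lines_used`.
#' @export
compute_spectra <- function(rf, mask = NULL, depth_range_mm = c(20, 100),
                            block_size = 32, window_mm = 6, overlap = 0.5,
                            frame = 1, nfft = 512) {
  n_lines <- rf$n_lines
  n_blocks <- n_lines %/% block_size
  if (n_blocks < 1) abort("`block_size` exceeds the number of RF lines.")
  dz <- diff(rf$depth_axis_mm[1:2])
  win <- round(window_mm / dz)
  step_mm <- window_mm * (1 - overlap)
  centers <- seq(depth_range_mm[1] + window_mm / 2,
                 depth_range_mm[2] - window_mm / 2, by = step_mm)
  centers <- centers[centers + window_mm / 2 <= max(rf$depth_axis_mm)]
  X <- t(matrix(rf$samples[, , frame], nrow = n_lines))    # samples x lines
  h <- hann_window(win)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(X), n_lines)
  freq <- (seq_len(nfft) - 1) / nfft * rf$fs_hz
  keep_f <- freq <= rf$fs_hz / 2
  pw <- matrix(NA_real_, length(centers), sum(keep_f))
  used <- 0L
  for (ci in seq_along(centers)) {
    i0 <- round((centers[ci] - window_mm / 2) / dz) + 1
    idx <- i0:(i0 + win - 1)
    seg <- X[idx, , drop = FALSE] * h
    mfrac <- colMeans(mask[idx, , drop = FALSE])
    block_p <- matrix(NA_real_, sum(keep_f), n_blocks)
    for (b in seq_len(n_blocks)) {
      lines_b <- (b - 1) * block_size + seq_len(block_size)
      ok <- lines_b[mfrac[lines_b] >= 0.5]
      if (length(ok) < block_size / 2) next
      P <- Mod(stats::mvfft(rbind(seg[, ok, drop = FALSE],
                                  matrix(0, nfft - win, length(ok)))))^2
      block_p[, b] <- rowMeans(P[keep_f, , drop = FALSE])
      used <- max(used, length(ok))
    }
    good_b <- colSums(!is.na(block_p)) > 0
    if (any(good_b)) {
      pw[ci, ] <- rowMeans(10 * log10(block_p[, good_b, drop = FALSE] + 1e-30))
    }
  }
  ok_rows <- rowSums(!is.na(pw)) > 0
  if (sum(ok_rows) < 2) abort("fewer than 2 usable depth windows; cannot form a spectral profile.")
  structure(list(power_db = pw[ok_rows, , drop = FALSE],
                 depth_axis_mm = centers[ok_rows],
                 freq_axis_hz = freq[keep_f],
                 n_lines_used = used * n_blocks,
                 block_size = block_size, n_blocks = n_blocks),
            class = "pocte_spectra")
}

#' @export
print.pocte_spectra <- function(x, ...) {
  cat(sprintf("<pocte_spectra> %d depth windows (%.0f-%.0f mm) x %d freq bins, %d lines used\n",
              nrow(x$power_db), min(x$depth_axis_mm), max(x$depth_axis_mm),
              ncol(x$power_db), x$n_lines_used))
  invisible(x)
}

#' Raw attenuation slope from spectral profiles
#'
#' Reference-phantom spectral-difference method: the log-spectral ratio
#' sample/reference is regressed on depth at every frequency bin of the
#' usable band (where the reference power sits within `band_db` of its
#' peak), the per-frequency attenuation `alpha(f) = -slope/2` (dB/cm, the
#' round-trip factor) is then regressed on frequency, and the resulting
#' slope is the raw attenuation coefficient (dB/cm/MHz) of the sample
#' relative to the reference. Ratioing adjacent depth windows and frequency
#' bins of the two profiles cancels depth-independent system response, gain
#' and diffraction effects. With `method = "adjacent"` the sample profile is
#' used alone (adjacent-frequency normalization without a reference
#' phantom), yielding an absolute raw slope.
#'
#' @param p sample [compute_spectra()] profile.
#' @param reference reference profile on identical axes (ignored for
#'   `method = "adjacent"`).
#' @param method `"reference"` (default) or `"adjacent"`.
#' @param band_db usable-band definition relative to the peak power.
#' @param min_band_mhz minimum usable bandwidth.
#' @return A `pocte_raw_atten`: `raw_slope_db_cm_mhz`, per-frequency tibble
#'   `per_freq`, `band_mhz`, `method`.
#' @export
estimate_raw_attenuation <- function(p, reference = NULL,
                                     method = c("reference", "adjacent"),
                                     band_db = 20, min_band_mhz = 1) {
  method <- match.arg(method)
  if (method == "reference") {
    if (is.null(reference)) abort("`reference` profile required for the reference-phantom method.")
    if (!isTRUE(all.equal(p$freq_axis_hz, reference$freq_axis_hz)) ||
        !isTRUE(all.equal(p$depth_axis_mm, reference$depth_axis_mm))) {
      abort("sample and reference profiles must share frequency and depth axes.")
    }
    # band where BOTH profiles hold power within band_db of their peaks, so
    # that swapping sample and reference negates the estimate exactly
    band_r <- colMeans(reference$power_db)
    band_s <- colMeans(p$power_db)
    usable <- which(band_r >= max(band_r) - band_db &
                      band_s >= max(band_s) - band_db)
    target <- p$power_db - reference$power_db
  } else {
    band_s <- colMeans(p$power_db)
    usable <- which(band_s >= max(band_s) - band_db)
    target <- p$power_db
  }
  f_mhz <- p$freq_axis_hz[usable] / 1e6
  if (diff(range(f_mhz)) < min_band_mhz) {
    abort(sprintf("usable band %.2f MHz is narrower than %g MHz.",
                  diff(range(f_mhz)), min_band_mhz))
  }
  depth_cm <- p$depth_axis_mm / 10
  slopes <- vapply(usable, function(j) {
    y <- target[, j]
    ok <- is.finite(y)
    if (sum(ok) < 2) return(NA_real_)
    unname(coef(lm(y[ok] ~ depth_cm[ok]))[2])
  }, numeric(1))
  alpha_f <- -slopes / 2                      # dB/cm at each frequency
  ok <- is.finite(alpha_f)
  fit <- lm(alpha_f[ok] ~ f_mhz[ok])
  structure(list(
    raw_slope_db_cm_mhz = unname(coef(fit)[2]),
    per_freq = tibble::tibble(freq_mhz = f_mhz[ok], alpha_db_cm = alpha_f[ok]),
    band_mhz = range(f_mhz), method = method
  ), class = "pocte_raw_atten")
}

#' Fit the attenuation calibration model
#'
#' Least-squares affine map from raw attenuation slopes to known attenuation
#' coefficients (dB/m at 3.5 MHz) of reference phantoms. At least two
#' distinct known values are required; residuals are stored.
#'
#' @param known_db_m known attenuation coefficients, dB/m at 3.5 MHz.
#' @param raw_slope matching raw slopes (dB/cm/MHz) from
#'   [estimate_raw_attenuation()] (numeric, or a list of results).
#' @return A `pocte_calibration`: `slope`, `intercept`, `points` tibble with
#'   residuals.
#' @export
fit_calibration <- function(known_db_m, raw_slope) {
  if (is.list(raw_slope)) {
    raw_slope <- vapply(raw_slope, function(r) r$raw_slope_db_cm_mhz, numeric(1))
  }
  if (length(known_db_m) != length(raw_slope)) {
    abort("`known_db_m` and `raw_slope` must have equal length.")
  }
  if (length(unique(known_db_m)) < 2) {
    abort("`known_db_m` needs at least 2 distinct reference values.")
  }
  if (length(unique(round(raw_slope, 10))) < 2) {
    abort("`raw_slope` values are degenerate; cannot fit a calibration line.")
  }
  fit <- lm(known_db_m ~ raw_slope)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    points = tibble::tibble(known_db_m = known_db_m, raw_slope = raw_slope,
                            residual = unname(resid(fit)))
  ), class = "pocte_calibration")
}

#' @export
print.pocte_calibration <- function(x, ...) {
  cat(sprintf("<pocte_calibration> dB/m = %.1f + %.1f x raw, %d reference points, RMS residual %.2f dB/m\n",
              x$intercept, x$slope, nrow(x$points),
              sqrt(mean(x$points$residual^2))))
  invisible(x)
}

#' Calibrated, clamped MAP value
#'
#' Applies the calibration model to a raw attenuation slope and clamps the
#' result to the reportable output range of 100-400 dB/m. The value is valid
#' only when the parenchyma mask qualified (> 80% liver); an unqualified
#' mask still reports the value, flagged invalid.
#'
#' @param raw_slope raw slope (dB/cm/MHz) or a
#'   [estimate_raw_attenuation()] result.
#' @param calib a [fit_calibration()] model.
#' @param mask a [parenchyma_mask()]; `NULL` counts as qualified (e.g. bare
#'   phantom studies).
#' @return A `pocte_map`: `map_db_m` in `[100, 400]`, `raw_slope`, `mask`,
#'   `valid`.
#' @export
map_value <- function(raw_slope, calib, mask = NULL) {
  if (inherits(raw_slope, "pocte_raw_atten")) raw_slope <- raw_slope$raw_slope_db_cm_mhz
  if (!inherits(calib, "pocte_calibration")) abort("`calib` must be a fitted calibration model.")
  val <- calib$intercept + calib$slope * raw_slope
  structure(list(
    map_db_m = clamp(val, 100, 400), uncapped_db_m = val,
    raw_slope = raw_slope, mask = mask,
    valid = is.null(mask) || isTRUE(mask$qualified)
  ), class = "pocte_map")
}

#' @export
print.pocte_map <- function(x, ...) {
  cat(sprintf("<pocte_map> %.0f dB/m%s\n", x$map_db_m,
              if (x$valid) "" else " [mask not qualified]"))
  invisible(x)
}

#' Build a MAP calibration from simulated reference phantoms
#'
#' Simulates homogeneous reference phantoms of known attenuation
#' coefficients, computes their spectral profiles, estimates raw slopes
#' against the first phantom (the running reference) and fits the affine
#' calibration. The returned object carries the reference profile needed to
#' process samples.
#'
#' @param reference_alphas known attenuation coefficients, dB/cm/MHz; the
#'   first one doubles as the running reference phantom.
#' @param mode acquisition mode for the reference acquisitions.
#' @param seed simulation seed.
#' @param center_freq_mhz frequency at which dB/m values are quoted.
#' @param ... passed to [simulate_rf()].
#' @return A `pocte_calibration` with an extra `reference_profile` field.
#' @export
build_map_calibration <- function(reference_alphas = c(0.5, 1.0),
                                  mode = acquisition_mode("standard"),
                                  seed = 1701, center_freq_mhz = 3.5, ...) {
  if (length(reference_alphas) < 2) abort("need at least two reference phantoms.")
  profiles <- lapply(seq_along(reference_alphas), function(i) {
    ph <- make_phantom(thickness_mm = c(skin = 0, subcutaneous = 0, liver = 140),
                       liver_atten = reference_alphas[i], seed = seed + i)
    rf <- simulate_rf(ph, mode, n_lines = 256, seed = seed + i,
                      depth_mm = 110, interface_amp = 0, ...)
    compute_spectra(rf)
  })
  raws <- vapply(profiles, function(p) {
    estimate_raw_attenuation(p, reference = profiles[[1]])$raw_slope_db_cm_mhz
  }, numeric(1))
  known <- reference_alphas * center_freq_mhz * 100   # dB/cm/MHz -> dB/m at fc
  calib <- fit_calibration(known, raws)
  calib$reference_profile <- profiles[[1]]
  calib$center_freq_mhz <- center_freq_mhz
  calib
}

#' One-shot MAP estimate from an RF acquisition
#'
#' Runs the full attenuation chain on a 256-line acquisition: B-mode
#' formation, parenchyma segmentation with the >80% qualification rule,
#' block-averaged spectra over 20-100 mm, raw slope against the calibration's
#' reference profile, and the calibrated clamped MAP value.
#'
#' @param rf a 256-line [simulate_rf()] series.
#' @param calib a [build_map_calibration()] model (with reference profile).
#' @param phantom optional ground-truth phantom for mask scoring.
#' @param ... passed to [compute_spectra()].
#' @return A `pocte_map`.
#' @export
estimate_map <- function(rf, calib, phantom = NULL, ...) {
  if (is.null(calib$reference_profile)) {
    abort("`calib` must carry a reference profile (see build_map_calibration()).")
  }
  bm <- form_bmode(rf)
  mask <- segment_parenchyma(bm, phantom = phantom)
  sp <- compute_spectra(rf, mask = mask$mask, ...)
  raw <- estimate_raw_attenuation(sp, reference = calib$reference_profile)
  map_value(raw, calib, mask = mask)
}
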