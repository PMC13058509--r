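# Elastography chain: displacement tracking -> elastogram -> rule-based
# quality control -> wave-trajectory detection -> Young's modulus.

#' Track axial motion and build an elastogram
#'
#' Windowed normalized cross-correlation between consecutive RF frames of a
#' single A-line, with parabolic sub-sample peak interpolation. The
#' frame-to-frame displacement is expressed as axial velocity (um/ms) on a
#' depth x slow-time grid restricted to the acquisition mode's measurement
#' range below the skin surface - the elastogram on which quality control and
#' trajectory detection operate. Windows whose correlation peak falls below
#' `corr_floor` are flagged and their value interpolated along depth.
#'
#' @param rf a [simulate_rf()] series with at least two frames.
#' @param window_mm correlation window length (about two pulse lengths).
#' @param overlap_frac window overlap fraction.
#' @param line which A-line to track.
#' @param max_lag_mm displacement search range between consecutive frames.
#' @param corr_floor normalized-correlation floor below which a window is
#'   declared decorrelated.
#' @param meas_range_mm depth range retained; defaults to the mode's.
#' @return A `pocte_elastogram`: matrix `m` (depth windows x frame pairs,
#'   um/ms), `depth_axis_mm`, `time_axis_ms`, `meas_range_mm`, and the
#'   fraction of decorrelated windows `dropout_frac`.
#' @export
track_displacement <- function(rf, window_mm = 1.5, overlap_frac = 0.75,
                               line = 1, max_lag_mm = 0.5, corr_floor = 0.5,
                               meas_range_mm = NULL) {
  n_frames <- dim(rf$samples)[3]
  if (n_frames < 2) abort("`rf` must contain at least two frames to track motion.")
  meas_range_mm <- meas_range_mm %||% rf$mode$meas_range_mm
  dz <- diff(rf$depth_axis_mm[1:2])
  win <- max(round(window_mm / dz), 8)
  step <- max(round(win * (1 - overlap_frac)), 1)
  max_lag <- max(round(max_lag_mm / dz), 2)
  M <- matrix(rf$samples[line, , ], nrow = dim(rf$samples)[2])    # samples x frames
  n_samp <- nrow(M)

  starts <- seq(1 + max_lag, n_samp - win - max_lag, by = step)
  centers <- rf$depth_axis_mm[starts] + (win / 2) * dz
  keep <- centers >= meas_range_mm[1] & centers < meas_range_mm[2]
  starts <- starts[keep]; centers <- centers[keep]
  if (!length(starts)) abort("no tracking windows fall inside the measurement range.")
  W <- length(starts)
  idx <- outer(seq_len(win) - 1L, starts, `+`)      # win x W index matrix
  lags <- -max_lag:max_lag
  dt_ms <- 1000 / rf$frame_rate_hz

  vel <- matrix(NA_real_, W, n_frames - 1)
  dropped <- 0L
  for (j in seq_len(n_frames - 1)) {
    X <- matrix(M[idx, j], win, W)
    X <- sweep(X, 2, colMeans(X))
    xn <- sqrt(colSums(X^2))
    ncc <- matrix(-Inf, length(lags), W)
    for (li in seq_along(lags)) {
      Y <- matrix(M[idx + lags[li], j + 1], win, W)
      Y <- sweep(Y, 2, colMeans(Y))
      yn <- sqrt(colSums(Y^2))
      ncc[li, ] <- colSums(X * Y) / pmax(xn * yn, .Machine$double.eps)
    }
    pk <- max.col(t(ncc), ties.method = "first")
    disp_samp <- numeric(W)
    good <- rep(TRUE, W)
    for (w in seq_len(W)) {
      p <- pk[w]
      if (ncc[p, w] < corr_floor) { good[w] <- FALSE; next }
      off <- if (p > 1 && p < length(lags)) {
        parabolic_offset(ncc[p - 1, w], ncc[p, w], ncc[p + 1, w])
      } else 0
      disp_samp[w] <- lags[p] + off
    }
    if (any(!good)) {
      dropped <- dropped + sum(!good)
      if (any(good)) {
        disp_samp[!good] <- approx(which(good), disp_samp[good],
                                   xout = which(!good), rule = 2)$y
      }
    }
    vel[, j] <- disp_samp * dz * 1000 / dt_ms   # mm -> um, per ms
  }
  structure(list(
    m = vel, depth_axis_mm = centers,
    time_axis_ms = (seq_len(n_frames - 1) - 0.5) * dt_ms,
    meas_range_mm = meas_range_mm,
    dropout_frac = dropped / (W * (n_frames - 1)),
    window_mm = window_mm
  ), class = "pocte_elastogram")
}

#' @export
print.pocte_elastogram <- function(x, ...) {
  cat(sprintf("<pocte_elastogram> %d depths x %d times, range %g-%g mm, peak |v| %.1f um/ms\n",
              nrow(x$m), ncol(x$m), x$meas_range_mm[1], x$meas_range_mm[2],
              max(abs(x$m))))
  invisible(x)
}

# first-crest ridge: per depth row, the time of the first local maximum
# reaching `frac` of the row maximum. Rows too weak relative to the map are
# marked invalid.
elastogram_ridge <- function(e, frac = 0.7, row_floor_frac = 0.25) {
  m <- e$m
  t_idx <- rep(NA_integer_, nrow(m))
  v_row <- apply(m, 1, max)
  # floor relative to a robust row-maximum scale, not the global max (a single
  # tracking spike must not disqualify deeper, amplitude-decayed rows)
  floor_v <- max(row_floor_frac * quantile(v_row, 0.9, names = FALSE),
                 .Machine$double.eps)
  for (r in seq_len(nrow(m))) {
    if (v_row[r] < floor_v) next
    x <- m[r, ]
    thr <- frac * v_row[r]
    n <- length(x)
    locmax <- which(x >= thr &
                      x >= c(-Inf, x[-n]) &
                      x >= c(x[-1], -Inf))
    if (length(locmax)) t_idx[r] <- locmax[1]
  }
  list(t_idx = t_idx, valid = !is.na(t_idx), v_row = v_row)
}

#' Default quality-control thresholds
#'
#' One threshold per criterion score; an elastogram passes QC only if every
#' score meets its threshold. The device's numeric thresholds are
#' unpublished; these defaults are calibrated so that clean simulated
#' acquisitions pass and constructed defects (gaps, noise-only maps) fail.
#'
#' @param intensity,length,linearity,continuity,parallelism,background_noise
#'   thresholds in `[0, 1]`.
#' @return Named numeric vector.
#' @export
qc_thresholds <- function(intensity = 0.5, length = 0.5, linearity = 0.5,
                          continuity = 0.75, parallelism = 0.5,
                          background_noise = 0.5) {
  c(intensity = intensity, length = length, linearity = linearity,
    continuity = continuity, parallelism = parallelism,
    background_noise = background_noise)
}

#' Rule-based elastogram quality control
#'
#' Scores the six criteria used to grade elastogram quality - signal
#' intensity, trajectory length, linearity, continuity, parallelism of the
#' primary wave trajectory, and background noise level - each in `[0, 1]`,
#' deterministically from the motion map. The primary trajectory is taken as
#' the first-crest ridge (first strong local maximum per depth row). An
#' elastogram passes when every score reaches its threshold; if no ridge is
#' detectable all trajectory-dependent scores are 0 and the exam fails QC.
#'
#' @param e a [track_displacement()] elastogram.
#' @param thresholds named vector from [qc_thresholds()].
#' @param intensity_ref velocity amplitude (um/ms) mapping the 95th
#'   percentile of `|m|` to an intensity score of 1.
#' @return A `pocte_qc` list: `scores` (named numeric), `passed`, `thresholds`.
#' @export
qc_elastogram <- function(e, thresholds = qc_thresholds(), intensity_ref = 20) {
  m <- e$m
  scores <- c(intensity = 0, length = 0, linearity = 0, continuity = 0,
              parallelism = 0, background_noise = 0)
  scores["intensity"] <- clamp(quantile(abs(m), 0.95, names = FALSE) / intensity_ref, 0, 1)
  ridge <- elastogram_ridge(e)
  valid <- ridge$valid
  if (sum(valid) >= 3) {
    rows <- which(valid)
    span <- range(rows)
    z <- e$depth_axis_mm[rows]
    t_ms <- e$time_axis_ms[ridge$t_idx[rows]]
    scores["length"] <- clamp(diff(range(e$depth_axis_mm[span])) /
                                diff(e$meas_range_mm), 0, 1)
    fit <- lm(z ~ t_ms)
    ss_res <- sum(resid(fit)^2)
    ss_tot <- sum((z - mean(z))^2)
    scores["linearity"] <- if (ss_tot > 0) clamp(1 - ss_res / ss_tot, 0, 1) else 0
    in_span <- seq(span[1], span[2])
    gaps <- rle(valid[in_span])
    gap_max <- if (any(!gaps$values)) max(gaps$lengths[!gaps$values]) else 0
    scores["continuity"] <- clamp(1 - gap_max / length(in_span), 0, 1)
    half <- rows <= median(rows)
    if (sum(half) >= 2 && sum(!half) >= 2) {
      s1 <- coef(lm(z[half] ~ t_ms[half]))[2]
      s2 <- coef(lm(z[!half] ~ t_ms[!half]))[2]
      scores["parallelism"] <- if (is.finite(s1) && is.finite(s2) &&
                                     abs(s1) + abs(s2) > 0) {
        clamp(1 - abs(s1 - s2) / (abs(s1) + abs(s2)), 0, 1)
      } else 0
    }
    # background = pre-arrival region (causality: silent before the
    # wavefront); on-ridge = within +-1 time bin of the fitted trajectory
    slope <- coef(fit)[2]
    if (is.finite(slope) && slope > 0) {
      t_pred <- (e$depth_axis_mm - coef(fit)[1]) / slope
      t_bin <- round(approx(e$time_axis_ms, seq_along(e$time_axis_ms),
                            xout = t_pred, rule = 2)$y)
      on <- pre <- matrix(FALSE, nrow(m), ncol(m))
      for (r in seq_len(nrow(m))) {
        on[r, intersect(seq(t_bin[r] - 1, t_bin[r] + 1), seq_len(ncol(m)))] <- TRUE
        if (t_bin[r] > 3) pre[r, seq_len(t_bin[r] - 3)] <- TRUE
      }
      on_rms <- sqrt(mean(m[on]^2))
      pre_rms <- if (any(pre)) sqrt(mean(m[pre]^2)) else 0
      scores["background_noise"] <- if (on_rms > 0) clamp(1 - pre_rms / on_rms, 0, 1) else 0
    }
  }
  passed <- all(scores >= thresholds[names(scores)])
  structure(list(scores = scores, passed = passed, thresholds = thresholds),
            class = "pocte_qc")
}

#' @export
print.pocte_qc <- function(x, ...) {
  cat("<pocte_qc>", if (x$passed) "PASSED" else "FAILED", "\n")
  print(round(x$scores, 3))
  invisible(x)
}

#' Detect the shear-wave trajectory on an elastogram
#'
#' Finds the dominant straight line in the motion map by an exhaustive
#' line-integral (Hough/Radon-style) transform: for every candidate slope in
#' `slope_range` (gridded uniformly in slowness so that timing resolution is
#' constant) and every onset time, the mean signed velocity along the line
#' `t(z) = t0 + (z - z0) / v` is computed; the global maximum identifies the
#' wavefront, whose slope is the shear-wave speed. The slope is refined by
#' parabolic interpolation of the slowness profile; ties break toward the
#' lower slope.
#'
#' @param e a [track_displacement()] elastogram.
#' @param slope_range physiologic search band, m/s.
#' @param fit_floor minimum peak-to-mean transform ratio; below it no
#'   trajectory is declared and an error is thrown.
#' @param onset_window_ms when positive, each depth row is masked to a causal
#'   window around its first strong crest before the transform, so the
#'   detected line is the primary (first-arriving) wave trajectory rather
#'   than any later reverberation of the 50-Hz cycle. Set to 0 to transform
#'   the raw map.
#' @return A `pocte_trajectory`: `slope_m_per_s`, `intercept_ms` (onset at
#'   the shallowest depth), `fit_score`.
#' @export
detect_trajectory <- function(e, slope_range = c(0.5, 5.0), fit_floor = 1.0,
                              onset_window_ms = 4) {
  m_raw <- e$m
  m <- e$m
  if (onset_window_ms > 0) {
    dt0 <- diff(e$time_axis_ms[1:2])
    pre <- max(round(1 / dt0), 1)
    post <- max(round(onset_window_ms / dt0), 1)
    for (r in seq_len(nrow(m))) {
      rmax <- max(m[r, ])
      if (rmax <= 0) { m[r, ] <- 0; next }
      first <- which(m[r, ] >= 0.5 * rmax)[1]
      keep <- seq(max(first - pre, 1), min(first + post, ncol(m)))
      mask <- rep(TRUE, ncol(m)); mask[keep] <- FALSE
      m[r, mask] <- 0
    }
  }
  z <- e$depth_axis_mm
  t_ms <- e$time_axis_ms
  z0 <- z[1]
  dt <- diff(t_ms[1:2])
  span <- diff(range(z))
  ds <- dt / span                                   # slowness step: <=1 bin skew
  s_grid <- seq(1 / slope_range[2], 1 / slope_range[1], by = ds)
  # slopes ascending so which.max ties resolve toward the lower slope
  s_grid <- rev(s_grid)
  n_t <- length(t_ms)
  score <- matrix(-Inf, length(s_grid), n_t)
  ti <- seq_len(n_t)
  for (si in seq_along(s_grid)) {
    shift_bins <- (z - z0) * s_grid[si] / dt
    acc <- matrix(0, nrow(m), n_t)
    for (r in seq_len(nrow(m))) {
      tq <- ti + shift_bins[r]
      i0 <- floor(tq); w <- tq - i0
      v0 <- ifelse(i0 >= 1 & i0 <= n_t, m[r, pmax(pmin(i0, n_t), 1)], NA)
      v1 <- ifelse(i0 + 1 >= 1 & i0 + 1 <= n_t, m[r, pmax(pmin(i0 + 1, n_t), 1)], NA)
      acc[r, ] <- (1 - w) * v0 + w * v1
    }
    score[si, ] <- colMeans(acc, na.rm = TRUE) *
      (colMeans(!is.na(acc)) >= 0.5)                # need half the depths on-grid
  }
  score[!is.finite(score)] <- -Inf
  prof <- apply(score, 1, max)
  best_s <- which.max(prof)
  best_t <- which.max(score[best_s, ])
  peak <- prof[best_s]
  # fit score: mean of the *raw* map along the detected line, relative to the
  # raw map RMS - a featureless map cannot push this ratio above ~0.5
  rms_raw <- sqrt(mean(m_raw^2))
  line_t <- t_ms[best_t] + (z - z0) * s_grid[best_s]
  line_v <- vapply(seq_along(z), function(r) {
    approx(t_ms, m_raw[r, ], xout = line_t[r], rule = 1)$y
  }, numeric(1))
  fit_score <- if (rms_raw > 0) mean(line_v, na.rm = TRUE) / rms_raw else 0
  if (!is.finite(peak) || !is.finite(fit_score) || fit_score < fit_floor) {
    abort(sprintf("no trajectory: peak-to-background ratio %.2f below floor %.2f.",
                  fit_score, fit_floor))
  }
  off <- if (best_s > 1 && best_s < length(s_grid)) {
    parabolic_offset(prof[best_s - 1], prof[best_s], prof[best_s + 1])
  } else 0
  s_ref <- s_grid[best_s] - off * ds                # grid is descending in s
  slope <- 1 / s_ref
  structure(list(slope_m_per_s = unname(slope),
                 intercept_ms = unname(t_ms[best_t]),
                 fit_score = unname(fit_score)),
            class = "pocte_trajectory")
}

#' @export
print.pocte_trajectory <- function(x, ...) {
  cat(sprintf("<pocte_trajectory> slope %.3f m/s, onset %.1f ms, fit score %.2f\n",
              x$slope_m_per_s, x$intercept_ms, x$fit_score))
  invisible(x)
}

#' Young's modulus from a wave-trajectory slope
#'
#' Converts the detected shear-wave speed to the ultrasonography-guided liver
#' stiffness measurement via `E = 3 rho c_s^2` (reported in kPa, with the TE
#' convention `rho` = 1000 kg/m3).
#'
#' @param trajectory a [detect_trajectory()] result, or a slope in m/s.
#' @param density_kg_m3 tissue density.
#' @param qc optional [qc_elastogram()] result carried through; the result is
#'   valid only if QC passed.
#' @return A `pocte_stiffness`: `shear_speed_m_s`, `youngs_modulus_kpa`,
#'   `qc`, `valid`.
#' @export
#' @examples
#' stiffness_from_slope(1.0)$youngs_modulus_kpa  # 3 kPa
stiffness_from_slope <- function(trajectory, density_kg_m3 = 1000, qc = NULL) {
  slope <- if (inherits(trajectory, "pocte_trajectory")) {
    trajectory$slope_m_per_s
  } else {
    trajectory
  }
  check_number(slope, "slope_m_per_s", len = 1)
  if (slope <= 0) abort("`slope_m_per_s` must be positive.")
  e_kpa <- 3 * density_kg_m3 * slope^2 / 1000
  structure(list(shear_speed_m_s = slope, youngs_modulus_kpa = e_kpa,
                 qc = qc, valid = if (is.null(qc)) TRUE else qc$passed),
            class = "pocte_stiffness")
}

#' @export
print.pocte_stiffness <- function(x, ...) {
  cat(sprintf("<pocte_stiffness> %.2f kPa (c_s %.3f m/s)%s\n",
              x$youngs_modulus_kpa, x$shear_speed_m_s,
              if (isTRUE(x$valid)) "" else " [QC failed]"))
  invisible(x)
}

#' One-shot stiffness estimate from an RF acquisition
#'
#' Convenience wrapper running the full chain: displacement tracking,
#' quality control, trajectory detection and modulus conversion. If QC fails
#' or no trajectory is found, the result is flagged invalid with `NA`
#' stiffness rather than erroring, matching the device behaviour of simply
#' discarding the acquisition.
#'
#' @inheritParams track_displacement
#' @param thresholds QC thresholds.
#' @param ... further arguments to [track_displacement()].
#' @return A `pocte_stiffness` (invalid with `NA` modulus when the
#'   acquisition is rejected).
#' @export
estimate_stiffness <- function(rf, thresholds = qc_thresholds(), ...) {
  e <- track_displacement(rf, ...)
  qc <- qc_elastogram(e, thresholds)
  if (!qc$passed) {
    return(structure(list(shear_speed_m_s = NA_real_,
                          youngs_modulus_kpa = NA_real_,
                          qc = qc, valid = FALSE),
                     class = "pocte_stiffness"))
  }
  traj <- tryCatch(detect_trajectory(e), error = function(err) NULL)
  if (is.null(traj)) {
    qc$passed <- FALSE
    return(structure(list(shear_speed_m_s = NA_real_,
                          youngs_modulus_kpa = NA_real_,
                          qc = qc, valid = FALSE),
                     class = "pocte_stiffness"))
  }
  stiffness_from_slope(traj, qc = qc)
}
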