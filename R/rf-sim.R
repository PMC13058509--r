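# Forward simulation: 50-Hz shear-wave propagation, RF speckle acquisition
# with frequency-linear attenuation, and B-mode formation.

#' Propagate the 50-Hz shear wave through a phantom
#'
#' Computes the axial displacement field `u(z, t)` (micrometres) induced by a
#' surface vibration of the mode's peak-to-peak amplitude: a travelling damped
#' sinusoid `u = A(z) sin(2 pi f (t - tau(z)))` for `t >= tau(z)` and zero
#' before the wavefront arrives (causality). The arrival time `tau(z)` is the
#' piecewise travel time at per-layer shear speed `c_s = sqrt(E / (3 rho))`,
#' and `A(z) = A(0) exp(-z / decay_mm)` models geometric/viscous amplitude
#' loss.
#'
#' @param phantom a [make_phantom()] object.
#' @param mode an [acquisition_mode()]; sets the surface amplitude.
#' @param duration_ms slow-time extent; at least two vibration periods (40 ms).
#' @param frame_rate_hz slow-time sampling rate; must exceed four times the
#'   vibration frequency.
#' @param dz_mm depth grid step.
#' @param depth_mm maximum depth simulated (defaults to the mode image depth).
#' @param decay_mm amplitude decay length of the travelling wave.
#' @param vibration_freq_hz vibrator frequency (50 Hz).
#' @return A `pocte_displacement` with matrix `u_um` (depth x slow time),
#'   `depth_axis_mm`, `time_axis_ms` and the generating parameters.
#' @export
propagate_shear_wave <- function(phantom, mode = acquisition_mode("standard"),
                                 duration_ms = 50, frame_rate_hz = 2000,
                                 dz_mm = 0.5, depth_mm = NULL, decay_mm = 60,
                                 vibration_freq_hz = 50) {
  if (duration_ms < 2000 / vibration_freq_hz) {
    abort("`duration_ms` must cover at least two vibration periods (>= 40 ms at 50 Hz).")
  }
  if (frame_rate_hz < 4 * vibration_freq_hz) {
    abort("`frame_rate_hz` below 4x the vibration frequency would alias the shear wave.")
  }
  depth_mm <- depth_mm %||% mode$image_depth_mm
  z <- seq(0, depth_mm, by = dz_mm)
  t_ms <- seq(0, duration_ms, by = 1000 / frame_rate_hz)
  tau <- shear_arrival_ms(phantom, z)
  amp0 <- mode$vibration_pp_mm / 2 * 1000      # p-p mm -> amplitude um
  amp <- amp0 * exp(-z / decay_mm)
  phase <- outer(-tau, t_ms, `+`)              # (t - tau) in ms
  u <- amp * sin(2 * pi * vibration_freq_hz / 1000 * phase)
  u[phase < 0] <- 0
  structure(list(u_um = u, depth_axis_mm = z, time_axis_ms = t_ms,
                 vibration_freq_hz = vibration_freq_hz,
                 frame_rate_hz = frame_rate_hz, decay_mm = decay_mm,
                 mode = mode),
            class = "pocte_displacement")
}

# linearly interpolate a displacement field at scatterer depths for one frame
interp_displacement <- function(disp, depth_mm, frame) {
  u <- disp$u_um[, frame]
  approx(disp$depth_axis_mm, u, xout = clamp(depth_mm, 0, max(disp$depth_axis_mm)),
         rule = 2)$y
}

#' Simulate an RF frame series from a phantom
#'
#' Generates speckle RF: random sub-resolution scatterers (fully developed
#' speckle, about 12+ per resolution cell) convolved with a Gaussian-modulated
#' 3.5-MHz pulse, with depth-cumulative frequency-linear attenuation applied
#' per layer. When a displacement field is supplied each frame's scatterers
#' are axially shifted by `u(z, t)` before convolution, producing the
#' slow-time motion that the elastography chain tracks. The lateral dimension
#' is modelled as independent A-lines on a rectilinear grid; scatterer
#' amplitudes are suppressed inside vessel disks.
#'
#' @param phantom a [make_phantom()] object.
#' @param mode an [acquisition_mode()].
#' @param displacement optional [propagate_shear_wave()] field; its slow-time
#'   axis defines the frames.
#' @param n_lines number of A-lines (256 for attenuation acquisitions, 1 for
#'   single-line elastography acquisitions).
#' @param seed speckle seed; identical seed and configuration give
#'   bit-identical output. Defaults to the phantom's seed.
#' @param depth_mm imaged depth (defaults to the mode image depth).
#' @param fs_hz RF sampling rate.
#' @param center_freq_hz transducer centre frequency.
#' @param fractional_bw Gaussian pulse fractional bandwidth (FWHM / centre).
#' @param scatterers_per_mm scatterer density per A-line per mm.
#' @param lateral_width_mm lateral extent spanned by the A-lines.
#' @param interface_amp amplitude of the coherent specular echo deposited at
#'   each layer interface (relative to unit speckle amplitude); makes the
#'   capsule visible on B-mode.
#' @param sound_speed_m_s compressional sound speed.
#' @param atten_bin_mm depth quantisation of the frequency-dependent
#'   attenuation filter.
#' @return A `pocte_rf` with array `samples` (lines x depth samples x frames),
#'   `depth_axis_mm`, acquisition metadata and provenance.
#' @export
simulate_rf <- function(phantom, mode = acquisition_mode("standard"),
                        displacement = NULL, n_lines = 256, seed = NULL,
                        depth_mm = NULL, fs_hz = 20e6, center_freq_hz = 3.5e6,
                        fractional_bw = 0.6, scatterers_per_mm = 16,
                        lateral_width_mm = 80, interface_amp = 25,
                        sound_speed_m_s = 1540, atten_bin_mm = 3) {
  seed <- seed %||% phantom$speckle_seed
  depth_mm <- depth_mm %||% mode$image_depth_mm
  dz <- sound_speed_m_s / (2 * fs_hz) * 1000        # mm per RF sample
  n_samp <- floor(depth_mm / dz)
  depth_axis <- (seq_len(n_samp) - 1) * dz
  n_frames <- if (is.null(displacement)) 1L else length(displacement$time_axis_ms)
  lateral <- if (n_lines == 1) 0 else
    seq(-lateral_width_mm / 2, lateral_width_mm / 2, length.out = n_lines)

  # pulse spectrum on the padded FFT grid (zero-phase, peak at lag 0)
  fc <- center_freq_hz
  sigma_f <- fractional_bw * fc / (2 * sqrt(2 * log(2)))
  n_pad <- stats::nextn(n_samp + 64, c(2, 3, 5))
  f <- (seq_len(n_pad) - 1) / n_pad * fs_hz
  f <- ifelse(f > fs_hz / 2, f - fs_hz, f)          # signed frequencies
  pulse_spec <- exp(-(abs(f) - fc)^2 / (2 * sigma_f^2))

  # scatterers (shared across frames); drawn per line
  sc <- with_seed(seed, {
    n_sc <- round(scatterers_per_mm * depth_mm)
    z <- matrix(runif(n_sc * n_lines, 0, depth_mm), n_sc, n_lines)
    a <- matrix(rnorm(n_sc * n_lines), n_sc, n_lines)
    list(z = z, a = a)
  })
  if (nrow(sc$z)) {
    lay <- array(layer_at_depth(phantom, sc$z), dim = dim(sc$z))
    amp <- sc$a * array(phantom$layers$echogenicity[lay], dim = dim(sc$z))
  } else {
    amp <- sc$a
  }
  if (nrow(phantom$vessels) && nrow(sc$z)) {
    lat_mat <- matrix(lateral, nrow(sc$z), n_lines, byrow = TRUE)
    inv <- in_vessel(phantom, lat_mat, sc$z)
    amp[inv] <- amp[inv] * 0.02
  }
  n_sc <- nrow(sc$z)
  sc_z <- as.vector(sc$z)
  sc_amp <- as.vector(amp)
  sc_line <- rep(seq_len(n_lines), each = n_sc)

  # interface echoes: coherent across lines, at the layer boundaries
  ib <- phantom$boundaries_mm[phantom$boundaries_mm > 0 &
                                phantom$boundaries_mm < depth_mm]
  if (!length(ib) || interface_amp <= 0) ib <- numeric()

  # per-frame axial shifts
  U <- NULL
  U_ib <- NULL
  if (!is.null(displacement)) {
    U <- vapply(seq_len(n_frames),
                function(fr) interp_displacement(displacement, sc_z, fr),
                numeric(length(sc_z)))
    if (length(ib)) {
      U_ib <- vapply(seq_len(n_frames),
                     function(fr) interp_displacement(displacement, ib, fr),
                     numeric(length(ib)))
      U_ib <- matrix(U_ib, nrow = length(ib))
    }
  }

  n_bins <- ceiling(depth_mm / atten_bin_mm)
  bin_of <- function(z) pmin(pmax(floor(z / atten_bin_mm) + 1L, 1L), n_bins)
  bin_centers <- (seq_len(n_bins) - 0.5) * atten_bin_mm
  A_bin <- cumulative_atten_db_mhz(phantom, bin_centers)
  f_mhz <- abs(f) / 1e6

  n_cols <- n_lines * n_frames
  acc <- matrix(0 + 0i, n_pad, n_cols)
  sc_bin <- bin_of(sc_z)
  ib_bin <- if (length(ib)) bin_of(ib) else integer()

  for (b in seq_len(n_bins)) {
    sel <- which(sc_bin == b)
    ksel <- which(ib_bin == b)
    if (!length(sel) && !length(ksel)) next
    pos <- col <- val <- vector("list", 2L)
    if (length(sel)) {
      if (is.null(U)) {
        pos[[1]] <- sc_z[sel]
        col[[1]] <- sc_line[sel]
      } else {
        pos[[1]] <- rep(sc_z[sel], n_frames) + as.vector(U[sel, , drop = FALSE]) / 1000
        col[[1]] <- rep(sc_line[sel], n_frames) +
          rep((seq_len(n_frames) - 1L) * n_lines, each = length(sel))
      }
      val[[1]] <- rep(sc_amp[sel], n_frames)
    }
    if (length(ksel)) {
      zb <- rep(rep(ib[ksel], each = n_lines), n_frames)
      if (!is.null(U_ib)) {
        # U_ib is interfaces x frames; expand to lines-fastest, frame-slowest
        zb <- zb + rep(as.vector(U_ib[ksel, , drop = FALSE]), each = n_lines) / 1000
      }
      pos[[2]] <- zb
      col[[2]] <- rep(seq_len(n_lines), times = length(ksel) * n_frames) +
        rep((seq_len(n_frames) - 1L) * n_lines, each = n_lines * length(ksel))
      val[[2]] <- rep(interface_amp, length(zb))
    }
    pos <- unlist(pos); col <- unlist(col); val <- unlist(val)
    # linear-interpolation deposition with accumulation over shared samples
    p <- pos / dz + 1
    ok <- p >= 1 & p < n_samp
    p <- p[ok]; col <- col[ok]; val <- val[ok]
    if (!length(p)) next
    i0 <- floor(p); w <- p - i0
    lin <- c((col - 1) * n_pad + i0, (col - 1) * n_pad + i0 + 1)
    vv <- c(val * (1 - w), val * w)
    agg <- rowsum(vv, lin)
    train <- matrix(0, n_pad, n_cols)
    train[as.numeric(rownames(agg))] <- agg
    filt <- pulse_spec * 10^(-A_bin[b] * f_mhz / 10)
    acc <- acc + stats::mvfft(train) * filt
  }
  rf_flat <- Re(stats::mvfft(acc, inverse = TRUE)) / n_pad
  rf_flat <- rf_flat[seq_len(n_samp), , drop = FALSE]

  samples <- array(0, dim = c(n_lines, n_samp, n_frames))
  for (fr in seq_len(n_frames)) {
    samples[, , fr] <- t(rf_flat[, (fr - 1L) * n_lines + seq_len(n_lines), drop = FALSE])
  }
  structure(list(
    samples = samples, n_lines = n_lines, depth_axis_mm = depth_axis,
    lateral_axis_mm = lateral, fs_hz = fs_hz,
    frame_rate_hz = if (is.null(displacement)) NA_real_ else displacement$frame_rate_hz,
    center_freq_hz = center_freq_hz, mode = mode,
    provenance = list(speckle_seed = seed, phantom_scd_mm = phantom$scd_mm,
                      n_frames = n_frames)
  ), class = "pocte_rf")
}

#' @export
print.pocte_rf <- function(x, ...) {
  cat(sprintf("<pocte_rf> %d line(s) x %d samples x %d frame(s), fs %.0f MHz, fc %.1f MHz, mode %s\n",
              x$n_lines, dim(x$samples)[2], dim(x$samples)[3],
              x$fs_hz / 1e6, x$center_freq_hz / 1e6, x$mode$name))
  invisible(x)
}

#' Form a B-mode image from an RF frame series
#'
#' Envelope detection (analytic-signal magnitude) followed by log compression
#' with the mode's overall gain. Layer interfaces appear as intensity steps.
#'
#' @param rf a [simulate_rf()] series.
#' @param frame which slow-time frame to image.
#' @param gain_db log-domain gain; defaults to the acquisition mode's gain.
#' @return A `pocte_bmode` with matrix `image_db` (depth x lateral),
#'   `depth_axis_mm`, `lateral_axis_mm`, `gain_db`.
#' @export
form_bmode <- function(rf, frame = 1, gain_db = NULL) {
  gain_db <- gain_db %||% rf$mode$gain_db
  x <- t(matrix(rf$samples[, , frame], nrow = rf$n_lines))
  env <- envelope_columns(x)
  img <- 20 * log10(env + 1e-12) + gain_db
  structure(list(image_db = img, depth_axis_mm = rf$depth_axis_mm,
                 lateral_axis_mm = rf$lateral_axis_mm, gain_db = gain_db,
                 mode = rf$mode),
            class = "pocte_bmode")
}

#' @export
print.pocte_bmode <- function(x, ...) {
  cat(sprintf("<pocte_bmode> %d x %d px, depth to %.0f mm, gain %.0f dB\n",
              nrow(x$image_db), ncol(x$image_db),
              max(x$depth_axis_mm), x$gain_db))
  invisible(x)
}
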