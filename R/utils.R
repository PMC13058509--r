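# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so simulation seeds never leak into user sessions.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# scalar checks with field-naming errors (validation contract used by all
# configuration constructors)
check_number <- function(x, field, lo = -Inf, hi = Inf, len = NULL) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be numeric and non-missing.", field))
  }
  if (!is.null(len) && length(x) != len) {
    abort(sprintf("`%s` must have length %d, got %d.", field, len, length(x)))
  }
  if (any(x < lo) || any(x > hi)) {
    abort(sprintf("`%s` must lie in [%s, %s].", field, format(lo), format(hi)))
  }
  invisible(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", field))
  }
  invisible(x)
}

# parabolic refinement of a discrete argmax: offset in bin units within
# (-0.5, 0.5) given the three values around the peak
parabolic_offset <- function(y_minus, y0, y_plus) {
  denom <- y_minus - 2 * y0 + y_plus
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) {
    return(0)
  }
  off <- 0.5 * (y_minus - y_plus) / denom
  clamp(off, -0.5, 0.5)
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

# analytic-signal envelope of each column via FFT
envelope_columns <- function(x) {
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(as.matrix(x))
  Mod(stats::mvfft(X * h, inverse = TRUE) / n)
}

iqr_over_median <- function(x) {
  m <- median(x)
  if (m == 0) return(0)
  unname(diff(quantile(x, c(0.25, 0.75), names = FALSE)) / m)
}
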