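# Shared fixtures, built once per test session (simulation is the expensive
# part; every consumer takes the same frozen objects).

fixture_cache <- new.env(parent = emptyenv())

shared_calibration <- function() {
  if (is.null(fixture_cache$calib)) {
    fixture_cache$calib <- build_map_calibration(c(0.5, 1.0), seed = 4242)
  }
  fixture_cache$calib
}

liver_only_phantom <- function(alpha = 0.5, kpa = 6, seed = 11) {
  make_phantom(thickness_mm = c(skin = 0, subcutaneous = 0, liver = 140),
               liver_kpa = kpa, liver_atten = alpha, seed = seed)
}

# a hand-built elastogram container for synthetic trajectory images
synthetic_elastogram <- function(m, dz_mm = 1, dt_ms = 0.5) {
  structure(list(
    m = m,
    depth_axis_mm = (seq_len(nrow(m)) - 1) * dz_mm + 25,
    time_axis_ms = (seq_len(ncol(m)) - 1) * dt_ms,
    meas_range_mm = c(25, 25 + nrow(m) * dz_mm),
    dropout_frac = 0, window_mm = 1.5
  ), class = "pocte_elastogram")
}

# independent brute-force line search: for every (slope, onset) on a dense
# grid, sum the map along the line with nearest-neighbour sampling; returns
# the argmax slope.  Deliberately distinct from the package's interpolating
# slowness-grid transform.
brute_force_line_slope <- function(e, slopes = seq(0.5, 5, by = 0.01)) {
  m <- e$m
  z <- e$depth_axis_mm
  t_ms <- e$time_axis_ms
  dt <- diff(t_ms[1:2])
  best <- c(score = -Inf, slope = NA)
  for (v in slopes) {
    for (t0i in seq_along(t_ms)) {
      tt <- t_ms[t0i] + (z - z[1]) / v
      ti <- round((tt - t_ms[1]) / dt) + 1
      ok <- ti >= 1 & ti <= ncol(m)
      if (mean(ok) < 0.5) next
      s <- mean(m[cbind(which(ok), ti[ok])])
      if (s > best["score"]) best <- c(score = s, slope = v)
    }
  }
  best[["slope"]]
}

# brute-force AUROC: concordant-pair fraction with ties counted 1/2
brute_force_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# rank-formula AUC used inside bootstrap loops (independent of the package's
# placement computation)
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  (mean(r[labels]) - (sum(labels) + 1) / 2) / sum(!labels)
}
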