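# Agreement and association statistics: Bland-Altman, ICC(A,1), correlation
# and regression, weighted kappa, Wilcoxon signed-rank, Kruskal-Wallis with
# Dunn post hoc.

#' Bland-Altman agreement analysis
#'
#' Mean difference (bias) and 95% limits of agreement between a benchmark
#' `x` and a comparison method `y`; differences are `y - x`, limits are
#' `bias +/- 1.96 SD`.
#'
#' @param x benchmark measurements.
#' @param y comparison measurements, paired to `x`.
#' @return A tibble: bias, loa_lo, loa_hi, sd_diff, n.
#' @export
#' @examples
#' bland_altman(c(1, 2, 3), c(2, 4, 6))  # bias 2, LoA (0.04, 3.96)
bland_altman <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) abort("Bland-Altman needs at least 2 complete pairs.")
  d <- y - x
  s <- sd(d)
  tibble::tibble(bias = mean(d), loa_lo = mean(d) - 1.96 * s,
                 loa_hi = mean(d) + 1.96 * s, sd_diff = s, n = length(d))
}

#' Intraclass correlation coefficient (absolute agreement, single measures)
#'
#' Two-way, absolute-agreement, single-measurement ICC - ICC(A,1) in the
#' McGraw-Wong taxonomy - from the standard mean-squares decomposition of the
#' subjects x raters table formed by the two paired measurement sets.
#' Systematic offsets between the methods are penalised, unlike Pearson
#' correlation.
#'
#' @param x,y paired measurements (two raters/methods, n subjects).
#' @return ICC value; `NA` with a warning when the total variance is zero.
#' @export
icc_agreement <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("ICC needs at least 3 complete pairs.")
  k <- 2
  dat <- cbind(x, y)
  if (max(dat) - min(dat) < .Machine$double.eps) {
    warn("zero total variance; ICC undefined.")
    return(NA_real_)
  }
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  grand <- mean(dat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((dat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= .Machine$double.eps) return(1)
  (msr - mse) / denom
}

#' Association between two measurement series
#'
#' Pearson correlation, Spearman midrank correlation, least-squares slope and
#' intercept of `y` on `x`, and R-squared.
#'
#' @param x,y paired measurements.
#' @return A tibble: pearson_r, spearman_rs, slope, intercept, r2, n.
#' @export
association <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("association needs at least 3 complete pairs.")
  if (sd(x) < .Machine$double.eps) {
    warn("zero variance in `x`; regression undefined.")
    return(tibble::tibble(pearson_r = NA_real_, spearman_rs = NA_real_,
                          slope = NA_real_, intercept = NA_real_,
                          r2 = NA_real_, n = length(x)))
  }
  r <- cor(x, y)
  rs <- cor(rank(x), rank(y))
  fit <- coef(lm(y ~ x))
  tibble::tibble(pearson_r = r, spearman_rs = rs, slope = unname(fit[2]),
                 intercept = unname(fit[1]), r2 = r^2, n = length(x))
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H test across groups (via
#' [stats::kruskal.test()]), followed by Dunn's rank-sum z statistics for
#' every group pair with two-sided p-values (unadjusted by default, matching
#' plain post hoc reporting; an adjustment method can be requested).
#'
#' @param values numeric outcomes.
#' @param groups group labels.
#' @param p_adjust adjustment method for pairwise p-values
#'   (see [stats::p.adjust()]); `"none"` by default.
#' @return A `pocte_kw` list: `H`, `df`, `p`, `pairwise` tibble.
#' @export
group_location_test <- function(values, groups, p_adjust = "none") {
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups.")
  if (any(table(groups) == 0)) abort("every group must be non-empty.")
  ok <- is.finite(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (length(unique(values)) == 1) {
    # all observations tied: no location information, H = 0 by convention
    lv <- levels(groups)
    pairs <- utils::combn(lv, 2)
    return(structure(list(
      H = 0, df = nlevels(groups) - 1L, p = 1,
      pairwise = tibble::tibble(group_a = pairs[1, ], group_b = pairs[2, ],
                                z = 0, p = 1)
    ), class = "pocte_kw"))
  }
  kw <- kruskal.test(values, groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  sigma2 <- n * (n + 1) / 12 - tie_corr
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  mean_r <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  z <- vapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    (mean_r[[a]] - mean_r[[b]]) /
      sqrt(sigma2 * (1 / n_g[[a]] + 1 / n_g[[b]]))
  }, numeric(1))
  p <- stats::p.adjust(2 * pnorm(-abs(z)), method = p_adjust)
  structure(list(
    H = unname(kw$statistic), df = unname(kw$parameter), p = kw$p.value,
    pairwise = tibble::tibble(group_a = pairs[1, ], group_b = pairs[2, ],
                              z = z, p = p)
  ), class = "pocte_kw")
}

#' @export
print.pocte_kw <- function(x, ...) {
  cat(sprintf("<pocte_kw> H = %.3f, df = %d, p = %.3g\n", x$H, x$df, x$p))
  invisible(x)
}

#' Weighted Cohen's kappa
#'
#' Chance-corrected agreement between two ordinal raters with linear
#' (default) or quadratic disagreement weights.
#'
#' @param a,b ratings as integers in `1..n_categories` (or factors).
#' @param n_categories number of ordinal categories.
#' @param weights `"linear"` or `"quadratic"`.
#' @return Kappa value; `NA` with a warning when both raters use a single
#'   category.
#' @export
weighted_kappa <- function(a, b, n_categories = NULL,
                           weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  if (is.factor(a)) a <- as.integer(a)
  if (is.factor(b)) b <- as.integer(b)
  ok <- complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) != length(b) || !length(a)) abort("`a` and `b` must be equal-length ratings.")
  n_categories <- n_categories %||% max(a, b)
  if (any(c(a, b) < 1 | c(a, b) > n_categories)) {
    abort("ratings outside 1..n_categories.")
  }
  if (length(unique(c(a, b))) < 2) {
    warn("single category used by both raters; kappa undefined.")
    return(NA_real_)
  }
  k <- n_categories
  d <- abs(outer(seq_len(k), seq_len(k), `-`))
  w <- if (weights == "linear") 1 - d / (k - 1) else 1 - (d / (k - 1))^2
  obs <- table(factor(a, levels = seq_len(k)), factor(b, levels = seq_len(k))) /
    length(a)
  pa <- rowSums(obs); pb <- colSums(obs)
  exp_tab <- outer(pa, pb)
  po <- sum(w * obs); pe <- sum(w * exp_tab)
  if (1 - pe < .Machine$double.eps) {
    warn("degenerate marginal distribution; kappa undefined.")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Wilcoxon signed-rank test for paired measurements
#'
#' Zero differences are dropped; the exact distribution is used for up to 25
#' non-zero differences without ties, otherwise the normal approximation
#' with tie correction. All-zero differences give a degenerate p = 1.
#'
#' @param x,y paired measurements.
#' @return A tibble: p, n_nonzero, degenerate.
#' @export
wilcoxon_signed <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  d <- y - x
  d <- d[d != 0]
  if (!length(d)) {
    return(tibble::tibble(p = 1, n_nonzero = 0L, degenerate = TRUE))
  }
  use_exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(wilcox.test(d, exact = use_exact, correct = TRUE))
  tibble::tibble(p = wt$p.value, n_nonzero = length(d), degenerate = FALSE)
}
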