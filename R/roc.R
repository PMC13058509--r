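# ROC analysis: midrank AUROC with DeLong variance, cutoff selection
# (Youden / fixed sensitivity / fixed specificity), confusion-matrix
# reconstruction, paired DeLong test, and the Hanley-McNeil sample-size
# projection.

# DeLong placement values: for each positive, the fraction of negatives it
# outranks (ties count 1/2), and vice versa.
delong_placements <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  n1 <- length(pos); n0 <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - r_pos) / n0            # per-positive placements
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_neg) / n1   # per-negative placements
  auc <- mean(v10)
  list(auc = auc, v10 = v10, v01 = v01, n1 = n1, n0 = n0,
       var = var(v10) / n1 + var(v01) / n0)
}

check_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.logical(labels)
  if (anyNA(labels)) abort("`labels` must be binary without missing values.")
  if (!any(labels) || all(labels)) abort("both classes must be present in `labels`.")
  labels
}

#' ROC curve and AUROC with DeLong variance
#'
#' Estimates the area under the ROC curve by the midrank (Mann-Whitney)
#' statistic, its variance from DeLong placement components, and a normal
#' 95% CI. The curve enumerates every distinct score as a cutoff with the
#' positive-call convention `value >= cutoff` (higher stiffness/attenuation
#' indicates disease).
#'
#' @param scores numeric marker values.
#' @param labels binary disease labels (logical, 0/1 or two-level factor).
#' @return A `pocte_roc`: `auroc`, `se`, `ci95`, `curve` tibble
#'   (cutoff, sens, spec, youden), `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auroc  # 0.75
roc_auc <- function(scores, labels) {
  labels <- check_labels(labels)
  if (length(scores) != length(labels)) abort("`scores` and `labels` lengths differ.")
  ok <- is.finite(scores)
  scores <- scores[ok]; labels <- labels[ok]
  labels <- check_labels(labels)
  pl <- delong_placements(scores, labels)
  se <- sqrt(pl$var)
  cuts <- sort(unique(scores))
  sens <- vapply(cuts, function(ct) mean(scores[labels] >= ct), numeric(1))
  spec <- vapply(cuts, function(ct) mean(scores[!labels] < ct), numeric(1))
  curve <- tibble::tibble(cutoff = cuts, sens = sens, spec = spec,
                          youden = sens + spec - 1)
  structure(list(
    auroc = pl$auc, se = se,
    ci95 = clamp(pl$auc + c(-1, 1) * qnorm(0.975) * se, 0, 1),
    curve = curve, n_pos = pl$n1, n_neg = pl$n0,
    placements = pl
  ), class = "pocte_roc")
}

#' @export
print.pocte_roc <- function(x, ...) {
  cat(sprintf("<pocte_roc> AUROC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auroc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' @method tidy pocte_roc
#' @export
tidy.pocte_roc <- function(x, ...) x$curve

#' @method glance pocte_roc
#' @export
glance.pocte_roc <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, se = x$se, ci_lo = x$ci95[1],
                 ci_hi = x$ci95[2], n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Operating cutoff selection on a ROC curve
#'
#' Chooses the cutoff by Youden's index (argmax of sens + spec - 1, ties
#' broken toward the lowest cutoff, which favours sensitivity), or by the
#' fixed-operating-point criteria: among cutoffs attaining sensitivity (or
#' specificity) of at least `q`, the one maximising the other rate. PPV and
#' NPV come from the empirical confusion matrix at the chosen cutoff.
#'
#' @param roc a [roc_auc()] result.
#' @param criterion `"youden"`, `"fixed_sens"` or `"fixed_spec"`.
#' @param q constraint level for the fixed criteria.
#' @return A `pocte_cutoff` tibble row: cutoff, sens, spec, ppv, npv,
#'   criterion.
#' @export
choose_cutoff <- function(roc, criterion = c("youden", "fixed_sens", "fixed_spec"),
                          q = 0.9) {
  criterion <- match.arg(criterion)
  cv <- roc$curve
  idx <- switch(
    criterion,
    youden = which.max(cv$youden),
    fixed_sens = {
      ok <- which(cv$sens >= q)
      if (!length(ok)) {
        abort(sprintf("no cutoff attains sensitivity >= %g (best attainable %.3f).",
                      q, max(cv$sens)))
      }
      ok[which.max(cv$spec[ok])]
    },
    fixed_spec = {
      ok <- which(cv$spec >= q)
      if (!length(ok)) {
        abort(sprintf("no cutoff attains specificity >= %g (best attainable %.3f).",
                      q, max(cv$spec)))
      }
      ok[which.max(cv$sens[ok])]
    })
  row <- cv[idx, ]
  tp <- row$sens * roc$n_pos
  fn <- roc$n_pos - tp
  tn <- row$spec * roc$n_neg
  fp <- roc$n_neg - tn
  out <- tibble::tibble(
    criterion = criterion, cutoff = row$cutoff, sens = row$sens,
    spec = row$spec,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
  class(out) <- c("pocte_cutoff", class(out))
  out
}

#' Confusion-matrix metrics from published rates
#'
#' Reconstructs fractional confusion-matrix counts and predictive values
#' from sensitivity, specificity and the class sizes - the arithmetic that
#' links a published diagnostic table's rate columns. Counts are kept
#' fractional; rounding belongs to reporting.
#'
#' @param sens,spec rates in `[0, 1]`.
#' @param n_pos,n_neg class sizes.
#' @return A tibble: tp, fp, tn, fn, ppv, npv, prevalence.
#' @export
#' @examples
#' confusion_from_rates(1.00, 0.54, 29, 107)[, c("ppv", "npv")]
confusion_from_rates <- function(sens, spec, n_pos, n_neg) {
  check_number(sens, "sens", 0, 1, 1); check_number(spec, "spec", 0, 1, 1)
  check_number(n_pos, "n_pos", lo = 1e-9, len = 1)
  check_number(n_neg, "n_neg", lo = 1e-9, len = 1)
  tp <- sens * n_pos; fn <- n_pos - tp
  tn <- spec * n_neg; fp <- n_neg - tn
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    prevalence = n_pos / (n_pos + n_neg))
}

#' Paired DeLong test for two correlated AUROCs
#'
#' Compares the AUROCs of two markers measured on the same patients against
#' the same labels, using the covariance of DeLong placement values. When
#' the rankings are identical (zero variance of the difference) the result
#' is degenerate with p = 1.
#'
#' @param scores_a,scores_b paired marker values.
#' @param labels shared binary labels.
#' @return A tibble: auroc_a, auroc_b, delta, z, p, degenerate.
#' @export
delong_paired <- function(scores_a, scores_b, labels) {
  labels <- check_labels(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    abort("`scores_a`, `scores_b` and `labels` must have equal length.")
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  var_diff <- var(pa$v10 - pb$v10) / pa$n1 + var(pa$v01 - pb$v01) / pa$n0
  delta <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    return(tibble::tibble(auroc_a = pa$auc, auroc_b = pb$auc, delta = delta,
                          z = 0, p = 1, degenerate = TRUE))
  }
  z <- delta / sqrt(var_diff)
  tibble::tibble(auroc_a = pa$auc, auroc_b = pb$auc, delta = delta,
                 z = z, p = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Sample size for estimating an AUROC
#'
#' Smallest n such that the Hanley-McNeil standard error of the expected
#' AUROC, at the given prevalence, does not exceed the target - the
#' projection used to size a diagnostic accuracy study. A CI-width variant
#' converts the full 95% CI width to an SE target (`width / (2 x 1.96)`).
#'
#' @param expected_auroc anticipated AUROC, in (0.5, 1).
#' @param se_target maximum standard error (e.g. 0.05).
#' @param prevalence disease prevalence in (0, 1).
#' @param ci_width alternatively, a target full 95% CI width.
#' @return Integer n.
#' @export
#' @examples
#' samplesize_auroc(0.80, se_target = 0.05, prevalence = 0.30)
samplesize_auroc <- function(expected_auroc, se_target = NULL, prevalence = 0.5,
                             ci_width = NULL) {
  check_number(expected_auroc, "expected_auroc", lo = 0.5 + 1e-9, hi = 1 - 1e-9, len = 1)
  check_number(prevalence, "prevalence", lo = 1e-9, hi = 1 - 1e-9, len = 1)
  if (is.null(se_target) && is.null(ci_width)) {
    abort("supply `se_target` or `ci_width`.")
  }
  if (is.null(se_target)) se_target <- ci_width / (2 * qnorm(0.975))
  check_number(se_target, "se_target", lo = 1e-9, len = 1)
  a <- expected_auroc
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  hm_var <- function(n) {
    n1 <- prevalence * n
    n0 <- (1 - prevalence) * n
    (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) / (n1 * n0)
  }
  n <- 4
  while (hm_var(n) > se_target^2) {
    n <- n + 1
    if (n > 1e7) abort("sample-size target unreachable.")
  }
  n
}
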