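# Measurement-count sufficiency analysis: per-patient median subsets of
# k = 1..10 repetitions (sequential or random selection) compared with the
# 10-measurement reference medians.

#' Per-patient median subsets of repeated measurements
#'
#' For each patient, takes the median of `k` of their repetitions: the first
#' `k` in acquisition order (sequential selection) or `k` drawn without
#' replacement under a cohort-level seed (random selection). Also returns the
#' subset IQR/median ratio per patient (zero when `k` = 1 by construction).
#'
#' @param reps patients x repetitions matrix (see [rep_matrix()]), or a
#'   [synth_cohort()] tibble together with `parameter`.
#' @param k subset size, `1..ncol(reps)`.
#' @param method `"sequential"` or `"random"`.
#' @param seed seed for random selection.
#' @param parameter repetition set to extract when `reps` is a cohort.
#' @return A tibble: patient row, `median`, `iqr_over_median`.
#' @export
median_subsets <- function(reps, k, method = c("sequential", "random"),
                           seed = 1, parameter = "usg_lsm") {
  method <- match.arg(method)
  if (is.data.frame(reps)) reps <- rep_matrix(reps, parameter)
  n_rep <- ncol(reps)
  if (k < 1 || k > n_rep) {
    abort(sprintf("`k` must lie in 1..%d.", n_rep))
  }
  picked <- if (method == "sequential" || k == n_rep) {
    matrix(rep(seq_len(k), nrow(reps)), nrow(reps), k, byrow = TRUE)
  } else {
    with_seed(seed, {
      do.call(rbind, lapply(seq_len(nrow(reps)),
                            function(i) sort(sample(n_rep, k))))
    })
  }
  med <- numeric(nrow(reps))
  iqr <- numeric(nrow(reps))
  for (i in seq_len(nrow(reps))) {
    v <- reps[i, picked[i, ]]
    med[i] <- median(v)
    iqr[i] <- if (k > 1) iqr_over_median(v) else 0
  }
  tibble::tibble(patient = seq_len(nrow(reps)), median = med,
                 iqr_over_median = iqr)
}

#' Measurement-count sufficiency table
#'
#' For every subset size `k` = 1..10, selection method and histologic
#' endpoint: the AUROC of the subset medians, the paired DeLong p-value
#' against the 10-measurement reference medians, and (per parameter and `k`)
#' the Bland-Altman bias and limits of agreement versus the reference
#' medians, ICC, Spearman correlation, Wilcoxon signed-rank p, and the
#' cohort-average IQR/median ratio. The `k = 10` rows are exact
#' self-comparisons (bias 0, ICC 1, degenerate tests).
#'
#' @param cohort a [synth_cohort()] tibble with stage labels and repetition
#'   columns.
#' @param endpoints named list mapping endpoint name to a logical vector or
#'   a function of the cohort returning labels; defaults to the five key
#'   endpoints (>=F2, F4 on stiffness; >=S1, >=S2, S3 on attenuation).
#' @param methods subset selection methods to evaluate.
#' @param seed seed for random selection (one draw per patient per `k`).
#' @param replicates number of random-selection draws averaged per `k`
#'   (metrics averaged across draws; 1 reproduces a single-draw table).
#' @param k_values subset sizes.
#' @return A tibble, one row per (method, parameter, k, endpoint), columns
#'   `auroc`, `ci_lo`, `ci_hi`, `delong_p_vs_ref`, `bias`, `loa_lo`,
#'   `loa_hi`, `icc`, `spearman_rs`, `wilcoxon_p`, `avg_iqr_over_median`.
#' @export
sufficiency_table <- function(cohort,
                              endpoints = NULL,
                              methods = c("sequential", "random"),
                              seed = 1, replicates = 1,
                              k_values = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!all(c("fibrosis_stage", "steatosis_grade") %in% names(cohort))) {
    abort("`cohort` must carry fibrosis_stage and steatosis_grade labels.")
  }
  stage_num <- as.integer(cohort$fibrosis_stage) - 1L
  grade_num <- as.integer(cohort$steatosis_grade) - 1L
  default_endpoints <- list(
    "usg_lsm.F2"  = stage_num >= 2,
    "usg_lsm.F4"  = stage_num >= 4,
    "map.S1"      = grade_num >= 1,
    "map.S2"      = grade_num >= 2,
    "map.S3"      = grade_num >= 3)
  endpoints <- endpoints %||% default_endpoints
  params <- unique(sub("\\..*", "", names(endpoints)))
  reps_list <- lapply(setNames(params, params), function(p) rep_matrix(cohort, p))
  k_values <- k_values %||% seq_len(ncol(reps_list[[1]]))

  rows <- list()
  for (method in methods) {
    for (p in params) {
      reps <- reps_list[[p]]
      n_rep <- ncol(reps)
      ref <- median_subsets(reps, n_rep, "sequential")$median
      eps <- endpoints[sub("\\..*", "", names(endpoints)) == p]
      for (k in k_values) {
        n_draws <- if (method == "random" && k < n_rep) replicates else 1
        acc_agree <- NULL
        acc_ep <- NULL
        for (d in seq_len(n_draws)) {
          sub <- median_subsets(reps, k, method, seed = seed + (d - 1) * 1000L)
          ba <- bland_altman(ref, sub$median)
          agree <- tibble::tibble(
            bias = ba$bias, loa_lo = ba$loa_lo, loa_hi = ba$loa_hi,
            icc = if (k == n_rep) 1 else icc_agreement(ref, sub$median),
            spearman_rs = if (k == n_rep) 1 else
              cor(rank(ref), rank(sub$median)),
            wilcoxon_p = wilcoxon_signed(ref, sub$median)$p,
            avg_iqr_over_median = mean(sub$iqr_over_median))
          ep_rows <- dplyr::bind_rows(lapply(names(eps), function(nm) {
            lab <- eps[[nm]]
            r_sub <- roc_auc(sub$median, lab)
            dl <- delong_paired(sub$median, ref, lab)
            tibble::tibble(endpoint = sub(".*\\.", "", nm),
                           auroc = r_sub$auroc, ci_lo = r_sub$ci95[1],
                           ci_hi = r_sub$ci95[2], delong_p_vs_ref = dl$p)
          }))
          acc_agree <- if (is.null(acc_agree)) agree else acc_agree + agree
          acc_ep <- if (is.null(acc_ep)) ep_rows else {
            acc_ep[, -1] <- acc_ep[, -1] + ep_rows[, -1]
            acc_ep
          }
        }
        agree <- acc_agree / n_draws
        ep_rows <- acc_ep
        ep_rows[, -1] <- ep_rows[, -1] / n_draws
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(method = method, parameter = p, k = k)[rep(1, nrow(ep_rows)), ],
          ep_rows, agree[rep(1, nrow(ep_rows)), ])
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pocte_sufficiency", class(out))
  out
}
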