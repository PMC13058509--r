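# Synthetic cohort generator: histologic stages, latent per-patient stiffness
# and attenuation, ten repeated measurements per device with calibrated
# repetition noise, paired conventional-device values with calibrated
# correlation and bias, and laboratory values for serum scores.

#' Cohort generator configuration
#'
#' Defines the synthetic biopsy/paired-TE population. Defaults emulate the
#' study cohort: fibrosis-stage prevalences 15/57/39/17/10 out of 138 and
#' steatosis-grade prevalences 10/43/54/29 out of 136; per-stage log-normal
#' true stiffness rising through the clinically used cut-off bands; repetition
#' noise tuned so the median IQR/median ratio is about 21% (point-of-care
#' LSM), 12% (conventional LSM) and 10% (both attenuation parameters); and
#' inter-device agreement targets (Pearson r 0.86 with +0.6 kPa bias for the
#' stiffness pair, r 0.80 with +29 dB/m bias for the attenuation pair)
#' realised by a shared-latent construction whose disagreement variance and
#' offset are solved from closed-form mixture moments.
#'
#' @param n number of patients.
#' @param fibrosis_prev,steatosis_prev prevalence vectors (sum to 1).
#' @param lsm_median_kpa per-stage median true stiffness (F0..F4), kPa.
#' @param lsm_sdlog within-stage log-SD of true stiffness.
#' @param map_mean_db_m per-grade mean true attenuation (S0..S3), dB/m.
#' @param map_sd_db_m within-grade SD of true attenuation.
#' @param rep_iqr ratio targets (median IQR/median) for repetition noise,
#'   named `usg_lsm`, `conv_lsm`, `map`, `cap`.
#' @param lsm_pair_r,lsm_pair_bias_kpa stiffness-pair Pearson correlation and
#'   mean bias (point-of-care minus conventional).
#' @param att_pair_r,att_pair_bias_db_m attenuation-pair targets.
#' @param allocation `"quota"` (largest-remainder exact counts) or
#'   `"multinomial"`.
#' @param missing_lab_rate fraction of patients with missing serology.
#' @param n_reps repetitions per device parameter.
#' @param seed generator seed.
#' @return A `pocte_cohort_config` list.
#' @export
cohort_config <- function(n = 138,
                          fibrosis_prev = c(F0 = 15, F1 = 57, F2 = 39, F3 = 17, F4 = 10) / 138,
                          steatosis_prev = c(S0 = 10, S1 = 43, S2 = 54, S3 = 29) / 136,
                          lsm_median_kpa = c(4.6, 6.2, 8.6, 11.5, 18.5),
                          lsm_sdlog = 0.30,
                          map_mean_db_m = c(215, 262, 280, 305),
                          map_sd_db_m = 28,
                          rep_iqr = c(usg_lsm = 0.21, conv_lsm = 0.12,
                                      map = 0.10, cap = 0.10),
                          lsm_pair_r = 0.86, lsm_pair_bias_kpa = 0.6,
                          att_pair_r = 0.80, att_pair_bias_db_m = 29,
                          allocation = c("quota", "multinomial"),
                          missing_lab_rate = 0.015, n_reps = 10, seed = 1L) {
  allocation <- match.arg(allocation)
  check_number(n, "n", lo = 2, len = 1)
  if (abs(sum(fibrosis_prev) - 1) > 1e-6) abort("`fibrosis_prev` must sum to 1.")
  if (abs(sum(steatosis_prev) - 1) > 1e-6) abort("`steatosis_prev` must sum to 1.")
  check_number(lsm_median_kpa, "lsm_median_kpa", lo = 0.1, len = 5)
  check_number(map_mean_db_m, "map_mean_db_m", lo = 1, len = 4)
  check_number(lsm_sdlog, "lsm_sdlog", lo = 1e-6, len = 1)
  check_number(map_sd_db_m, "map_sd_db_m", lo = 0, len = 1)
  check_number(rep_iqr, "rep_iqr", lo = 0, hi = 1, len = 4)
  structure(list(
    n = as.integer(n), fibrosis_prev = fibrosis_prev,
    steatosis_prev = steatosis_prev, lsm_median_kpa = lsm_median_kpa,
    lsm_sdlog = lsm_sdlog, map_mean_db_m = map_mean_db_m,
    map_sd_db_m = map_sd_db_m, rep_iqr = rep_iqr,
    lsm_pair_r = lsm_pair_r, lsm_pair_bias_kpa = lsm_pair_bias_kpa,
    att_pair_r = att_pair_r, att_pair_bias_db_m = att_pair_bias_db_m,
    allocation = allocation, missing_lab_rate = missing_lab_rate,
    n_reps = as.integer(n_reps), seed = as.integer(seed)
  ), class = "pocte_cohort_config")
}

# expected sample IQR (type-7 quantiles) of n standard-normal draws, as a
# fraction of the population IQR; the finite-sample IQR is biased low and the
# repetition-noise calibration must target the *observed* 10-rep statistic.
sample_iqr_bias <- local({
  cache <- new.env(parent = emptyenv())
  function(n_reps) {
    key <- as.character(n_reps)
    if (is.null(cache[[key]])) {
      cache[[key]] <- with_seed(20260928, {
        sims <- matrix(rnorm(20000 * n_reps), ncol = n_reps)
        mean(apply(sims, 1, function(x) diff(quantile(x, c(0.25, 0.75), names = FALSE))))
      }) / (2 * qnorm(0.75))
    }
    cache[[key]]
  }
})

# multiplicative log-normal repetition noise: sdlog such that the observed
# per-patient IQR/median of n_reps repetitions targets the given ratio
sdlog_for_iqr <- function(iqr_target, n_reps = 10) {
  if (iqr_target <= 0) return(0)
  asinh(iqr_target / 2) / qnorm(0.75) / sample_iqr_bias(n_reps)
}

# SD of the log of the sample median of n_reps log-normal deviates
# (asymptotic: var of the sample median of N(0, s^2) is pi s^2 / (2 n))
median_noise_sdlog <- function(sdlog_rep, n_reps) {
  sdlog_rep * sqrt(pi / (2 * n_reps))
}

# Closed-form mixture moments for X = exp(L + u), Y = c exp(L + d + v),
# L stage-mixture normal, u/d/v independent zero-mean normals.
# Returns the device-disagreement SD and scale delivering the target raw-scale
# Pearson r and mean bias E[X] - E[Y].
solve_interdevice_lognormal <- function(w, mu, sd_within, s_u, s_v,
                                        target_r, target_bias) {
  EX <- sum(w * exp(mu + (sd_within^2 + s_u^2) / 2))
  EX2 <- sum(w * exp(2 * mu + 2 * (sd_within^2 + s_u^2)))
  VX <- EX2 - EX^2
  r_of <- function(s_d) {
    EY1 <- sum(w * exp(mu + (sd_within^2 + s_d^2 + s_v^2) / 2))
    EY2 <- sum(w * exp(2 * mu + 2 * (sd_within^2 + s_d^2 + s_v^2)))
    EXY <- sum(w * exp(2 * mu + 2 * sd_within^2)) *
      exp((s_u^2 + s_d^2 + s_v^2) / 2)
    (EXY - EX * EY1) / sqrt(VX * (EY2 - EY1^2))
  }
  if (r_of(1e-8) < target_r) {
    s_d <- 1e-8   # even zero disagreement cannot reach the target; use minimum
  } else {
    s_d <- uniroot(function(s) r_of(s) - target_r, c(1e-8, 2))$root
  }
  EY1 <- sum(w * exp(mu + (sd_within^2 + s_d^2 + s_v^2) / 2))
  scale <- (EX - target_bias) / EY1
  list(s_d = s_d, scale = scale)
}

# additive-normal analogue for the attenuation pair
solve_interdevice_normal <- function(w, mu, sd_within, s_u, s_v,
                                     target_r, target_bias) {
  m <- sum(w * mu)
  VT <- sum(w * (mu - m)^2) + sd_within^2
  need <- VT^2 / (target_r^2 * (VT + s_u^2)) - VT - s_v^2
  s_d <- sqrt(max(need, 0))
  list(s_d = s_d, offset = -target_bias)
}

#' Generate a synthetic patient cohort
#'
#' Draws histologic stages (quota allocation reproduces the configured counts
#' exactly), per-patient latent true stiffness and attenuation, ten noisy
#' repetitions per device parameter, conventional-device medians coupled to
#' the same latent truth with the configured correlation and bias, and
#' laboratory values whose distributions shift with fibrosis stage so serum
#' scores carry diagnostic signal. All draws are reproducible under the seed.
#'
#' @param config a [cohort_config()].
#' @return A tibble (`pocte_cohort`), one row per patient, with repetition
#'   columns `usg_lsm_rep_1..n` and `map_rep_1..n`, per-patient medians,
#'   conventional-device values `conv_lsm_kpa` / `conv_cap_db_m`, stage
#'   factors and labs.
#' @export
#' @examples
#' coh <- synth_cohort(cohort_config(n = 138, seed = 1))
#' table(coh$fibrosis_stage)
synth_cohort <- function(config = cohort_config()) {
  cfg <- config
  n <- cfg$n
  with_seed(cfg$seed, {
    stage <- draw_stages(cfg$fibrosis_prev, n, cfg$allocation)   # 0..4
    grade <- draw_stages(cfg$steatosis_prev, n, cfg$allocation)  # 0..3

    s_rep_u <- sdlog_for_iqr(cfg$rep_iqr[["usg_lsm"]], cfg$n_reps)
    s_rep_c <- sdlog_for_iqr(cfg$rep_iqr[["conv_lsm"]], cfg$n_reps)
    s_med_u <- median_noise_sdlog(s_rep_u, cfg$n_reps)
    s_med_c <- median_noise_sdlog(s_rep_c, cfg$n_reps)
    mu_stage <- log(cfg$lsm_median_kpa)
    sol <- solve_interdevice_lognormal(
      w = cfg$fibrosis_prev, mu = mu_stage, sd_within = cfg$lsm_sdlog,
      s_u = s_med_u, s_v = s_med_c,
      target_r = cfg$lsm_pair_r, target_bias = cfg$lsm_pair_bias_kpa)

    L <- mu_stage[stage + 1] + rnorm(n, 0, cfg$lsm_sdlog)
    true_lsm <- exp(L)
    usg_reps <- true_lsm * matrix(rlnorm(n * cfg$n_reps, 0, s_rep_u), n)
    conv_latent <- sol$scale * exp(L + rnorm(n, 0, sol$s_d))
    conv_reps <- conv_latent * matrix(rlnorm(n * cfg$n_reps, 0, s_rep_c), n)

    s_rep_m <- sdlog_for_iqr(cfg$rep_iqr[["map"]], cfg$n_reps)
    s_rep_cap <- sdlog_for_iqr(cfg$rep_iqr[["cap"]], cfg$n_reps)
    mu_grade <- cfg$map_mean_db_m
    att_mean <- sum(cfg$steatosis_prev * mu_grade)
    s_u_att <- att_mean * median_noise_sdlog(s_rep_m, cfg$n_reps)
    s_v_att <- att_mean * median_noise_sdlog(s_rep_cap, cfg$n_reps)
    sol_a <- solve_interdevice_normal(
      w = cfg$steatosis_prev, mu = mu_grade, sd_within = cfg$map_sd_db_m,
      s_u = s_u_att, s_v = s_v_att,
      target_r = cfg$att_pair_r, target_bias = cfg$att_pair_bias_db_m)

    true_map <- mu_grade[grade + 1] + rnorm(n, 0, cfg$map_sd_db_m)
    true_map <- clamp(true_map, 110, 390)
    map_reps <- clamp(true_map * matrix(rlnorm(n * cfg$n_reps, 0, s_rep_m), n),
                      100, 400)
    cap_latent <- true_map + sol_a$offset + rnorm(n, 0, sol_a$s_d)
    cap_reps <- clamp(cap_latent * matrix(rlnorm(n * cfg$n_reps, 0, s_rep_cap), n),
                      100, 400)

    labs <- draw_labs(n, stage)

    out <- tibble::tibble(
      id = sprintf("P%04d", seq_len(n)),
      fibrosis_stage = factor(paste0("F", stage), levels = paste0("F", 0:4)),
      steatosis_grade = factor(paste0("S", grade), levels = paste0("S", 0:3)),
      true_lsm_kpa = true_lsm, true_map_db_m = true_map)
    for (j in seq_len(cfg$n_reps)) out[[paste0("usg_lsm_rep_", j)]] <- usg_reps[, j]
    for (j in seq_len(cfg$n_reps)) out[[paste0("map_rep_", j)]] <- map_reps[, j]
    out$usg_lsm_kpa <- apply(usg_reps, 1, median)
    out$map_db_m <- apply(map_reps, 1, median)
    out$usg_lsm_iqr_median <- apply(usg_reps, 1, iqr_over_median)
    out$map_iqr_median <- apply(map_reps, 1, iqr_over_median)
    out$conv_lsm_kpa <- apply(conv_reps, 1, median)
    out$conv_cap_db_m <- apply(cap_reps, 1, median)
    out$conv_lsm_iqr_median <- apply(conv_reps, 1, iqr_over_median)
    out$conv_cap_iqr_median <- apply(cap_reps, 1, iqr_over_median)
    out <- dplyr::bind_cols(out, labs)
    if (cfg$missing_lab_rate > 0) {
      miss <- runif(n) < cfg$missing_lab_rate
      out$ast_iu_l[miss] <- NA_real_
      out$alt_iu_l[miss] <- NA_real_
    }
    class(out) <- c("pocte_cohort", class(out))
    attr(out, "config") <- cfg
    out
  })
}

# stage draw: quota = largest-remainder exact counts, shuffled; multinomial =
# independent draws
draw_stages <- function(prev, n, allocation) {
  k <- length(prev)
  if (allocation == "quota") {
    raw <- prev * n
    counts <- floor(raw)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    sample(rep(seq_len(k) - 1L, times = counts))
  } else {
    sample(seq_len(k) - 1L, n, replace = TRUE, prob = prev)
  }
}

# labs with stage-dependent shifts so serum fibrosis scores are informative
draw_labs <- function(n, stage) {
  sex <- ifelse(runif(n) < 0.71, "male", "female")
  age <- round(clamp(rnorm(n, 46 + 2 * stage, 11), 18, 80))
  bmi <- round(clamp(rnorm(n, 27, 4), 17, 45), 1)
  diabetes <- runif(n) < clamp(0.10 + 0.02 * stage, 0, 1)
  ast <- round(exp(log(32) + 0.16 * stage + rnorm(n, 0, 0.45)), 0)
  alt <- round(pmax(ast * exp(rnorm(n, 0.15 - 0.06 * stage, 0.30)), 5), 0)
  platelets <- round(clamp(rnorm(n, 245 - 22 * stage, 48), 50, 450))
  albumin <- round(clamp(rnorm(n, 4.65 - 0.08 * stage, 0.32), 2.5, 5.5), 2)
  glucose <- round(clamp(rnorm(n, 5.3, 0.8) + 1.8 * diabetes, 3.5, 15), 1)
  tibble::tibble(age = age, sex = sex, bmi = bmi, diabetes = diabetes,
                 ast_iu_l = ast, alt_iu_l = alt,
                 platelets_10e9_l = platelets, albumin_g_dl = albumin,
                 glucose_mmol_l = glucose)
}

#' Serum comparator scores
#'
#' Computes the four serum indices used as non-invasive comparators, from
#' their original published formulas:
#' FIB-4 = age x AST / (platelets x sqrt(ALT));
#' APRI = (AST / 40 IU/L) / platelets x 100;
#' NFS = -1.675 + 0.037 age + 0.094 BMI + 1.13 diabetes + 0.99 AST/ALT
#'       - 0.013 platelets - 0.66 albumin (g/dL);
#' HSI = 8 ALT/AST + BMI (+2 if diabetic, +2 if female).
#' Missing labs propagate to missing scores (the patient is excluded from
#' score-based analyses).
#'
#' @param data a data frame with columns `age`, `sex`, `bmi`, `diabetes`,
#'   `ast_iu_l`, `alt_iu_l`, `platelets_10e9_l`, `albumin_g_dl` (e.g. a
#'   [synth_cohort()] tibble).
#' @return The input tibble with `fib4`, `apri`, `nfs`, `hsi` columns added.
#' @export
#' @examples
#' comparator_scores(tibble::tibble(
#'   age = 60, sex = "male", bmi = 30, diabetes = FALSE,
#'   ast_iu_l = 40, alt_iu_l = 40, platelets_10e9_l = 200,
#'   albumin_g_dl = 4.5))$fib4
comparator_scores <- function(data) {
  need <- c("age", "sex", "bmi", "diabetes", "ast_iu_l", "alt_iu_l",
            "platelets_10e9_l", "albumin_g_dl")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing lab columns: ", paste(missing_cols, collapse = ", ")))
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    fib4 = .data$age * .data$ast_iu_l /
      (.data$platelets_10e9_l * sqrt(.data$alt_iu_l)),
    apri = (.data$ast_iu_l / 40) / .data$platelets_10e9_l * 100,
    nfs = -1.675 + 0.037 * .data$age + 0.094 * .data$bmi +
      1.13 * as.numeric(.data$diabetes) + 0.99 * .data$ast_iu_l / .data$alt_iu_l -
      0.013 * .data$platelets_10e9_l - 0.66 * .data$albumin_g_dl,
    hsi = 8 * .data$alt_iu_l / .data$ast_iu_l + .data$bmi +
      2 * as.numeric(.data$diabetes) + 2 * (.data$sex == "female")
  )
}

#' Repetition-measurement matrix of a cohort
#'
#' @param cohort a [synth_cohort()] tibble.
#' @param parameter `"usg_lsm"` or `"map"`.
#' @return Numeric matrix, patients x repetitions, in acquisition order.
#' @export
rep_matrix <- function(cohort, parameter = c("usg_lsm", "map")) {
  parameter <- match.arg(parameter)
  cols <- grep(paste0("^", parameter, "_rep_\\d+$"), names(cohort), value = TRUE)
  cols <- cols[order(as.integer(sub(".*_rep_", "", cols)))]
  if (!length(cols)) abort(sprintf("no repetition columns found for %s.", parameter))
  as.matrix(cohort[cols])
}
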