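# Cohort-level diagnostic report and the end-to-end demo pipeline.

#' Diagnostic accuracy report for a cohort
#'
#' For each requested histologic endpoint, computes prevalence, AUROC with
#' DeLong 95% CI, and the operating points selected by Youden's index and by
#' the fixed sensitivity >= 0.9 / fixed specificity >= 0.9 criteria, with
#' sensitivity, specificity, PPV and NPV at each cutoff - the structure of a
#' diagnostic test characteristics table.
#'
#' @param cohort a [synth_cohort()] tibble.
#' @param endpoints character subset of `"F1"`, `"F2"`, `"F3"`, `"F4"`
#'   (stiffness endpoints, >= the stage except F4 itself) and `"S1"`,
#'   `"S2"`, `"S3"` (attenuation endpoints).
#' @param q fixed-operating-point constraint level.
#' @return A tibble, one row per endpoint x criterion.
#' @export
dxstats_report <- function(cohort, endpoints = c("F2", "F4", "S1", "S2", "S3"),
                           q = 0.9) {
  stage_num <- as.integer(cohort$fibrosis_stage) - 1L
  grade_num <- as.integer(cohort$steatosis_grade) - 1L
  rows <- lapply(endpoints, function(ep) {
    kind <- substr(ep, 1, 1)
    lvl <- as.integer(substr(ep, 2, 2))
    if (kind == "F") {
      labels <- stage_num >= lvl
      scores <- cohort$usg_lsm_kpa
      marker <- "usg_lsm_kpa"
    } else {
      labels <- grade_num >= lvl
      scores <- cohort$map_db_m
      marker <- "map_db_m"
    }
    roc <- roc_auc(scores, labels)
    crit <- lapply(c("youden", "fixed_sens", "fixed_spec"), function(cr) {
      tryCatch(choose_cutoff(roc, cr, q = q), error = function(err) NULL)
    })
    dplyr::bind_cols(
      tibble::tibble(endpoint = ep, marker = marker,
                     prevalence = mean(labels), auroc = roc$auroc,
                     ci_lo = roc$ci95[1], ci_hi = roc$ci95[2])[
                       rep(1, sum(!vapply(crit, is.null, logical(1)))), ],
      dplyr::bind_rows(crit))
  })
  dplyr::bind_rows(rows)
}

#' Run the end-to-end demonstration pipeline
#'
#' Wires every stage together on synthetic inputs: two demonstration
#' phantoms (standard and enhanced morphotypes) are examined with the full
#' protocol; a synthetic cohort is generated; the diagnostic accuracy report
#' and the measurement-count sufficiency tables are computed. All artifacts
#' (exam JSON, cohort CSV, report CSVs, run manifest) are written under
#' `out_dir`, and identical seeds reproduce identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; all stage seeds derive from it.
#' @param n_cohort cohort size.
#' @param run_exams simulate the two phantom exams (the slowest stage).
#' @param calibration optional pre-built [build_map_calibration()]; built
#'   from reference phantoms when omitted and exams are requested.
#' @return Invisibly, a list with the in-memory results and `manifest`.
#' @export
run_pipeline <- function(out_dir, seed = 1, n_cohort = 200, run_exams = TRUE,
                         calibration = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  manifest <- list(tool = "pocte", version = "0.1.0", seed = seed,
                   n_cohort = n_cohort, started = format(Sys.time(), tz = "UTC"))
  results <- list()

  if (run_exams) {
    if (is.null(calibration)) {
      calibration <- build_map_calibration(seed = seed + 900L)
    }
    write_calibration(calibration, file.path(out_dir, "calibration.json"))
    phantoms <- list(
      standard = make_phantom(scd_mm = 17, liver_kpa = 5.5, liver_atten = 0.55,
                              seed = seed + 10L),
      enhanced = make_phantom(scd_mm = 23, liver_kpa = 9.0, liver_atten = 0.75,
                              seed = seed + 20L))
    exams <- lapply(names(phantoms), function(nm) {
      ex <- run_exam(phantoms[[nm]], seed = seed + match(nm, names(phantoms)),
                     calibration = calibration)
      out <- c(glance(ex), list(acquisitions = ex$acquisitions))
      jsonlite::write_json(out, file.path(out_dir, paste0("exam_", nm, ".json")),
                           auto_unbox = TRUE, digits = NA, na = "null")
      ex
    })
    names(exams) <- names(phantoms)
    results$exams <- exams
    manifest$exams <- lapply(exams, function(e) glance(e))
  }

  cohort <- synth_cohort(cohort_config(n = n_cohort, seed = seed + 100L))
  cohort <- comparator_scores(cohort)
  write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
  results$cohort <- cohort

  report <- dxstats_report(cohort)
  write.csv(as.data.frame(report), file.path(out_dir, "dxstats_report.csv"),
            row.names = FALSE)
  results$dxstats <- report

  suff <- sufficiency_table(cohort, seed = seed + 200L)
  write.csv(as.data.frame(suff), file.path(out_dir, "repetition_report.csv"),
            row.names = FALSE)
  results$sufficiency <- suff

  manifest$outputs <- list.files(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
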