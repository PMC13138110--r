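cohort_csv_columns <- c("patient_id", "cycle", "structure_id",
                        "structure_type", "time_h", "doserate_gy_per_h",
                        "aa_gbq", "volume_cm3", "response")

#' Write / read a cohort sample table as CSV
#'
#' Long format, one row per dose-rate sample, columns `patient_id`, `cycle`
#' (1-based), `structure_id`, `structure_type` (`tumor`/`kidney`), `time_h`,
#' `doserate_gy_per_h`, `aa_gbq`, `volume_cm3`, `response`. Values round-trip
#' at full double precision. For a generated cohort the configuration is
#' serialized to JSON alongside (`<path>.config.json`).
#'
#' @param cohort a `lutadose_cohort` object or a sample data.frame.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  samples <- if (inherits(cohort, "lutadose_cohort")) cohort$samples else cohort
  data.table::fwrite(samples[, cohort_csv_columns], path)
  if (inherits(cohort, "lutadose_cohort")) {
    cfg <- cohort$config
    cfg$response <- unclass(cfg$response)
    jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_cohort
#' @return `read_cohort()`: the sample data.frame, validated against the
#'   schema (missing required columns are an error; unknown columns produce
#'   a warning and are kept; rows with non-finite numeric fields are an
#'   error naming the first offending row).
#' @export
read_cohort <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  miss <- setdiff(cohort_csv_columns, names(df))
  if (length(miss) > 0)
    lutadose_input_error(paste("cohort CSV missing required column(s):",
                               paste(miss, collapse = ", ")))
  extra <- setdiff(names(df), cohort_csv_columns)
  if (length(extra) > 0)
    warning(paste("ignoring unknown cohort CSV column(s):",
                  paste(extra, collapse = ", ")), call. = FALSE)
  num_cols <- c("cycle", "time_h", "doserate_gy_per_h", "aa_gbq", "volume_cm3")
  for (cn in num_cols) {
    bad <- which(!is.finite(as.numeric(df[[cn]])))
    if (length(bad) > 0)
      lutadose_input_error(sprintf(
        "cohort CSV column `%s` has a non-numeric/missing value at data row %d",
        cn, bad[1]))
  }
  df[, c(cohort_csv_columns, extra)]
}

#' End-to-end dosimetric dose-response pipeline
#'
#' Generates (or loads) a cohort, fits every structure-cycle dose-rate
#' curve, builds patient-level dose summaries, and runs the dose-response
#' analyses: the grouped sigmoid model in cAD, cross-validated two-feature
#' logistic and RBF-SVM classifiers, single-feature reference AUCs, the
#' cyclic-change summary, and rank statistics comparing responders with
#' nonresponders.
#'
#' @param config a [cohort_config()] (generate mode), or a path to a cohort
#'   CSV written by [write_cohort()] (load mode).
#' @param group_size patients per dose-response group (default 11).
#' @param cv_folds,cv_seed cross-validation folds and fold-assignment seed;
#'   `cv_seed` defaults to the cohort seed (load mode: 1).
#' @param output_dir optional directory; when given, all report tables and
#'   model JSONs are written there via [write_report()].
#' @return list of class `lutadose_report`: `samples`, `fits`,
#'   `patient_summary`, `groups_cad` (+ `sigmoid_cad` fit), `cyclic`,
#'   `classifiers` (logistic/svm/cad_only/delta_only evals), `rank_stats`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, group_size = 11, cv_folds = 5,
                         cv_seed = NULL, output_dir = NULL) {
  if (is.character(config)) {
    samples <- read_cohort(config)
    cohort <- NULL
    seed_used <- if (is.null(cv_seed)) 1L else cv_seed
    input_mode <- "load"
  } else {
    cohort <- generate_cohort(config)
    samples <- cohort$samples
    seed_used <- if (is.null(cv_seed)) config$seed else cv_seed
    input_mode <- "generate"
  }

  fits <- fit_cohort_doserates(samples)
  responses <- unique(samples[, c("patient_id", "response")])
  summary <- summarize_cohort(fits, responses)
  n_excluded <- attr(summary, "n_excluded")
  message(sprintf("pipeline: %d patients summarized, %d excluded (no lesion >= 10 cm^3), %d/%d fits clamped",
                  nrow(summary), n_excluded, sum(fits$clamped), nrow(fits)))

  is_pr <- summary$response == "PR"
  groups_cad <- group_patients(summary$cad_gy, is_pr, group_size)
  sig <- fit_sigmoid(groups_cad)
  groups_delta <- group_patients(summary$delta_adaa_pct, is_pr, group_size)

  adaa_cols <- grep("^adaa_c", names(summary), value = TRUE)
  med_adaa <- vapply(adaa_cols, function(cn) median(summary[[cn]]), numeric(1))
  cyc <- cyclic_changes(med_adaa)
  succ_per_patient <- apply(as.matrix(summary[, adaa_cols]), 1, function(v)
    cyclic_changes(v)$successive)
  cyclic <- list(median_adaa_per_cycle = unname(med_adaa),
                 median_pct_vs_cycle1 = cyc$vs_cycle1,
                 median_successive_decline_pct =
                   median(-as.vector(succ_per_patient)))

  classifiers <- lapply(
    setNames(nm = c("logistic", "svm", "cad_only", "delta_only")),
    function(m) crossval_auc(m, summary$cad_gy, summary$delta_adaa_pct,
                             summary$responder, n_folds = cv_folds,
                             seed = seed_used))

  rank_stats <- list(
    cad_resp_vs_nonresp = rank_test(summary$cad_gy[summary$responder],
                                    summary$cad_gy[!summary$responder]),
    delta_resp_vs_nonresp = rank_test(
      summary$delta_adaa_pct[summary$responder],
      summary$delta_adaa_pct[!summary$responder]),
    adaa_c1_vs_final = rank_test(summary[[adaa_cols[1]]],
                                 summary[[adaa_cols[length(adaa_cols)]]],
                                 paired = TRUE),
    cad_delta_spearman = spearman_test(summary$cad_gy,
                                       summary$delta_adaa_pct))

  report <- structure(list(
    samples = samples, cohort = cohort, fits = fits,
    patient_summary = summary,
    groups_cad = groups_cad, sigmoid_cad = sig,
    groups_delta = groups_delta,
    cyclic = cyclic, classifiers = classifiers, rank_stats = rank_stats,
    manifest = list(input_mode = input_mode, seed = seed_used,
                    group_size = group_size, cv_folds = cv_folds,
                    n_patients = nrow(summary), n_excluded = n_excluded,
                    n_fits = nrow(fits), n_clamped = sum(fits$clamped),
                    package_version = as.character(utils::packageVersion("lutadose")),
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "lutadose_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.lutadose_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("177Lu-DOTATATE dose-response report (%s mode, seed %s)\n",
              m$input_mode, m$seed))
  cat(sprintf("  %d patients (%d excluded), %d curve fits (%d clamped)\n",
              m$n_patients, m$n_excluded, m$n_fits, m$n_clamped))
  cat(sprintf("  sigmoid(cAD): Pmax = %.1f%%, Dhalf = %.1f Gy, k = %.1f Gy (R^2 = %.2f, RMSE = %.1f%%)\n",
              x$sigmoid_cad$pmax, x$sigmoid_cad$dhalf, x$sigmoid_cad$k,
              x$sigmoid_cad$quality$r_squared, x$sigmoid_cad$quality$rmse))
  cat(sprintf("  median successive AD/AA decline: %.1f%% per cycle\n",
              x$cyclic$median_successive_decline_pct))
  aucs <- vapply(x$classifiers, `[[`, numeric(1), "auc")
  cat(sprintf("  cross-validated AUC: %s\n",
              paste(sprintf("%s=%.3f", names(aucs), aucs), collapse = " ")))
  invisible(x)
}

#' Write a pipeline report bundle to a directory
#'
#' Emits `cohort.csv` (generate mode), `fits.csv`, `patient_summary.csv`,
#' `groups_cad.csv`, `models.json` (sigmoid parameters and fit quality,
#' classifier AUCs, fold assignments, ROC points, rank statistics) and
#' `manifest.json`.
#'
#' @param report a `lutadose_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$cohort))
    write_cohort(report$cohort, file.path(dir, "cohort.csv"))
  data.table::fwrite(report$fits, file.path(dir, "fits.csv"))
  data.table::fwrite(report$patient_summary,
                     file.path(dir, "patient_summary.csv"))
  data.table::fwrite(report$groups_cad, file.path(dir, "groups_cad.csv"))
  models <- list(
    sigmoid_cad = list(pmax = report$sigmoid_cad$pmax,
                       dhalf = report$sigmoid_cad$dhalf,
                       k = report$sigmoid_cad$k,
                       r_squared = report$sigmoid_cad$quality$r_squared,
                       rmse = report$sigmoid_cad$quality$rmse),
    classifiers = lapply(report$classifiers, function(cl)
      list(auc = cl$auc, fold_auc = cl$fold_auc, folds = cl$folds,
           seed = cl$seed, roc = cl$roc)),
    cyclic = report$cyclic,
    rank_stats = report$rank_stats)
  jsonlite::write_json(models, file.path(dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
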