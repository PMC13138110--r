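#' @importFrom data.table as.data.table fread fwrite
NULL

.datatable.aware <- TRUE

#' Fit every structure-cycle dose-rate curve in a cohort sample table
#'
#' Applies [fit_biexponential()] to each (patient, structure, cycle) group of
#' a long-format sample table and integrates each fit to an absorbed dose.
#'
#' @param samples long-format data.frame with columns `patient_id`, `cycle`,
#'   `structure_id`, `structure_type`, `time_h`, `doserate_gy_per_h`,
#'   `aa_gbq`, `volume_cm3` (and optionally `response`), as produced by
#'   [generate_cohort()] or read by [read_cohort()].
#' @return data.frame with one row per structure-cycle: identifiers plus `A`,
#'   `lambda1`, `lambda2`, `washout_halftime_h`, `uptake_halftime_h`,
#'   `ad_gy`, `adaa` (= ad_gy / aa_gbq), `aa_gbq`, `volume_cm3`, `clamped`,
#'   `sse`.
#' @export
fit_cohort_doserates <- function(samples) {
  need <- c("patient_id", "cycle", "structure_id", "structure_type",
            "time_h", "doserate_gy_per_h", "aa_gbq", "volume_cm3")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0)
    lutadose_input_error(paste("samples table missing column(s):",
                               paste(miss, collapse = ", ")))
  dt <- data.table::as.data.table(samples)
  fit_one <- function(time_h, doserate, aa, vol) {
    fit <- fit_biexponential(time_h, doserate)
    ht <- half_times(fit)
    list(A = fit$A, lambda1 = fit$lambda1, lambda2 = fit$lambda2,
         washout_halftime_h = ht[["washout_h"]],
         uptake_halftime_h = ht[["uptake_h"]],
         ad_gy = fit$ad_gy, adaa = fit$ad_gy / aa[1],
         aa_gbq = aa[1], volume_cm3 = vol[1],
         clamped = fit$clamped, sse = fit$residual_sse)
  }
  out <- dt[, fit_one(time_h, doserate_gy_per_h, aa_gbq, volume_cm3),
            by = c("patient_id", "structure_id", "structure_type", "cycle")]
  as.data.frame(out)
}

#' Patient-level dose summaries for a whole cohort
#'
#' Applies lesion eligibility filtering and [summarize_patient()] to every
#' patient of a fitted cohort, producing the analysis table of the
#' dose-response stage.
#'
#' @param fits fit table from [fit_cohort_doserates()].
#' @param responses optional data.frame with `patient_id` and `response`
#'   columns (taken from the sample table's `response` column if present
#'   there instead).
#' @param min_volume_cm3 lesion eligibility threshold, cm^3.
#' @return data.frame with one row per patient retaining at least one
#'   eligible lesion: `patient_id`, `n_lesions`, `adaa_c<k>` and `ad_c<k>`
#'   per cycle, `cad_gy`, `delta_adaa_pct`, `response`, `responder`.
#'   Patients whose lesions are all below threshold are dropped; the number
#'   dropped is attached as attribute `n_excluded`.
#' @export
summarize_cohort <- function(fits, responses = NULL, min_volume_cm3 = 10) {
  tum <- fits[fits$structure_type == "tumor", , drop = FALSE]
  kid <- fits[fits$structure_type == "kidney", , drop = FALSE]
  if (is.null(responses) && "response" %in% names(fits))
    responses <- unique(fits[, c("patient_id", "response")])
  pids <- unique(tum$patient_id)
  rows <- list()
  n_excluded <- 0L
  for (pid in pids) {
    ptum <- tum[tum$patient_id == pid, , drop = FALSE]
    elig_ids <- unique(eligible_lesions(
      data.frame(structure_id = ptum$structure_id,
                 volume_cm3 = ptum$volume_cm3),
      min_volume_cm3)$structure_id)
    if (length(elig_ids) == 0) { n_excluded <- n_excluded + 1L; next }
    ptum <- ptum[ptum$structure_id %in% elig_ids, , drop = FALSE]
    pkid <- kid[kid$patient_id == pid, , drop = FALSE]
    resp <- NA_character_
    if (!is.null(responses)) {
      m <- responses$response[responses$patient_id == pid]
      if (length(m) > 0) resp <- m[1]
    }
    s <- summarize_patient(
      lesion_doses = data.frame(lesion_id = ptum$structure_id,
                                cycle = ptum$cycle, ad_gy = ptum$ad_gy,
                                aa_gbq = ptum$aa_gbq),
      kidney_doses = if (nrow(pkid) > 0)
        data.frame(cycle = pkid$cycle, ad_gy = pkid$ad_gy,
                   aa_gbq = pkid$aa_gbq) else NULL,
      response = resp, patient_id = pid)
    row <- data.frame(patient_id = pid, n_lesions = s$n_lesions,
                      stringsAsFactors = FALSE)
    for (k in seq_along(s$cycles)) {
      row[[paste0("adaa_c", s$cycles[k])]] <- s$mean_adaa[k]
      row[[paste0("ad_c", s$cycles[k])]] <- s$mean_ad_gy[k]
    }
    if (!is.null(s$kidney_adaa))
      for (k in seq_along(s$kidney_adaa))
        row[[paste0("kidney_adaa_c", k)]] <- s$kidney_adaa[k]
    row$cad_gy <- s$cad_gy
    row$delta_adaa_pct <- s$delta_adaa_pct
    row$response <- s$response
    row$responder <- s$responder
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0)
    lutadose_input_error("no patient has an eligible lesion; nothing to summarize")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}
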