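#' Filter lesions by the dosimetric eligibility threshold
#'
#' Small structures carry large partial-volume uncertainty even after
#' recovery-coefficient correction, so lesions enter the dosimetry analysis
#' only if their volume on the first-cycle scan is at least `min_volume_cm3`
#' (boundary inclusive).
#'
#' @param lesions data.frame with at least a `volume_cm3` column (cycle-1
#'   volumes).
#' @param min_volume_cm3 inclusion threshold, cm^3 (default 10).
#' @return the eligible subset, original order preserved.
#' @export
eligible_lesions <- function(lesions, min_volume_cm3 = 10) {
  if (!"volume_cm3" %in% names(lesions))
    lutadose_input_error("lesions must carry a `volume_cm3` column")
  lesions[lesions$volume_cm3 >= min_volume_cm3, , drop = FALSE]
}

#' Percent cyclic changes of a per-cycle metric
#'
#' @param per_cycle_values numeric vector of a per-cycle metric (e.g. mean
#'   tumor AD/AA), cycle 1 first; length >= 2.
#' @return list with `vs_cycle1` (percent change of cycles 2..n relative to
#'   cycle 1) and `successive` (percent change of each cycle relative to the
#'   previous one), both of length `n - 1`.
#' @examples
#' cyclic_changes(c(3.2, 3.1, 2.4, 2.1))
#' @export
cyclic_changes <- function(per_cycle_values) {
  n <- length(per_cycle_values)
  if (n < 2) lutadose_input_error("at least 2 cycles are required")
  if (per_cycle_values[1] == 0)
    lutadose_input_error("cycle-1 value is zero; relative change undefined")
  if (any(per_cycle_values[-n] == 0))
    lutadose_input_error("zero value in cycle series; successive change undefined")
  v <- per_cycle_values
  list(vs_cycle1 = (v[-1] / v[1] - 1) * 100,
       successive = (v[-1] / v[-n] - 1) * 100)
}

#' Summarize a patient's lesion and kidney doses into trial metrics
#'
#' Patient-level metrics are unweighted arithmetic means across eligible
#' lesions at each cycle: mean absorbed dose (AD), mean AD per administered
#' activity (AD/AA), the cumulative absorbed dose cAD (sum over cycles of the
#' per-cycle mean AD), and the uptake-decline biomarker
#' \eqn{\Delta AD/AA = (AD/AA_{n} - AD/AA_1)/AD/AA_1 \times 100} between the
#' first and final cycles.
#'
#' @param lesion_doses data.frame with columns `lesion_id`, `cycle`, `ad_gy`,
#'   `aa_gbq` for the patient's eligible lesions, every cycle present for
#'   every lesion.
#' @param kidney_doses optional data.frame with `cycle`, `ad_gy`, `aa_gbq`
#'   for the (combined) kidneys.
#' @param response RECIST best-response label: `"CR"`, `"PR"`, `"SD"` or
#'   `"PD"`.
#' @param patient_id identifier carried into the output.
#' @return an object of class `patient_dose_summary`: list with `patient_id`,
#'   `n_lesions`, per-cycle `mean_ad_gy` and `mean_adaa` vectors, `cad_gy`,
#'   `delta_adaa_pct`, `pct_vs_cycle1`, `pct_successive`, kidney per-cycle
#'   `kidney_adaa` (or NULL), `response` and `responder` (TRUE iff CR or PR).
#' @export
summarize_patient <- function(lesion_doses, kidney_doses = NULL,
                              response = NA_character_,
                              patient_id = NA_character_) {
  need <- c("lesion_id", "cycle", "ad_gy", "aa_gbq")
  if (!all(need %in% names(lesion_doses)))
    lutadose_input_error(paste("lesion_doses must have columns:",
                               paste(need, collapse = ", ")))
  if (nrow(lesion_doses) == 0)
    lutadose_input_error("no eligible lesions")
  cycles <- sort(unique(lesion_doses$cycle))
  for (lid in unique(lesion_doses$lesion_id)) {
    have <- lesion_doses$cycle[lesion_doses$lesion_id == lid]
    miss <- setdiff(cycles, have)
    if (length(miss) > 0)
      lutadose_input_error(sprintf("lesion %s is missing cycle(s) %s",
                                   lid, paste(miss, collapse = ", ")))
  }
  mean_ad <- vapply(cycles, function(cc)
    mean(lesion_doses$ad_gy[lesion_doses$cycle == cc]), numeric(1))
  mean_adaa <- vapply(cycles, function(cc) {
    d <- lesion_doses[lesion_doses$cycle == cc, ]
    mean(d$ad_gy / d$aa_gbq)
  }, numeric(1))
  ch <- cyclic_changes(mean_adaa)
  nlast <- length(cycles)
  kid <- NULL
  if (!is.null(kidney_doses) && nrow(kidney_doses) > 0) {
    kord <- order(kidney_doses$cycle)
    kid <- kidney_doses$ad_gy[kord] / kidney_doses$aa_gbq[kord]
  }
  structure(list(
    patient_id = patient_id,
    n_lesions = length(unique(lesion_doses$lesion_id)),
    cycles = cycles,
    mean_ad_gy = mean_ad,
    mean_adaa = mean_adaa,
    cad_gy = sum(mean_ad),
    delta_adaa_pct = (mean_adaa[nlast] - mean_adaa[1]) / mean_adaa[1] * 100,
    pct_vs_cycle1 = ch$vs_cycle1,
    pct_successive = ch$successive,
    kidney_adaa = kid,
    response = response,
    responder = isTRUE(response %in% c("CR", "PR"))),
    class = "patient_dose_summary")
}

#' @export
print.patient_dose_summary <- function(x, ...) {
  cat(sprintf("Patient %s: %d lesion(s), cAD = %.1f Gy, dAD/AA = %+.1f%%, response %s\n",
              x$patient_id, x$n_lesions, x$cad_gy, x$delta_adaa_pct, x$response))
  invisible(x)
}

#' Kidney-dose-driven administered-activity adaptation
#'
#' The trial's activity-personalisation rule: the first cycle is standardized
#' to `first_aa_gbq`; after each cycle the kidney dose delivered so far is
#' computed from the measured per-cycle kidney AD/AA, the activity required
#' to deliver the remaining dose to the `kidney_target_gy` target is divided
#' equally over the remaining cycles using the most recent cycle's kidney
#' AD/AA, and the result is capped at `cap_gbq`.
#'
#' @param kidney_adaa_history measured kidney AD/AA (Gy/GBq), one value per
#'   completed cycle. Empty vector = before the first cycle.
#' @param aa_history administered activities (GBq) of the completed cycles;
#'   same length as `kidney_adaa_history`.
#' @param n_total_cycles planned number of cycles.
#' @param kidney_target_gy cumulative kidney absorbed-dose target (default
#'   23 Gy).
#' @param first_aa_gbq standardized first-cycle activity (default 7.4 GBq).
#' @param cap_gbq per-cycle activity cap (default 11.1 GBq).
#' @return recommended administered activity for the next cycle, GBq (never
#'   negative; 0 if the target has been reached).
#' @examples
#' # cycle-1 kidney AD/AA at the cohort median: the cap binds
#' adapt_activity(0.43, 7.4, n_total_cycles = 4)
#' @export
adapt_activity <- function(kidney_adaa_history, aa_history,
                           n_total_cycles = 4, kidney_target_gy = 23,
                           first_aa_gbq = 7.4, cap_gbq = 11.1) {
  if (length(kidney_adaa_history) != length(aa_history))
    lutadose_input_error("kidney_adaa_history and aa_history must have equal length")
  n_done <- length(aa_history)
  if (n_done == 0) return(first_aa_gbq)
  if (n_done >= n_total_cycles)
    lutadose_input_error("all cycles already completed")
  if (any(kidney_adaa_history <= 0))
    lutadose_input_error("kidney AD/AA must be positive")
  if (any(aa_history <= 0))
    lutadose_input_error("administered activities must be positive")
  delivered <- sum(aa_history * kidney_adaa_history)
  remaining_ad <- max(0, kidney_target_gy - delivered)
  per_cycle_ad <- remaining_ad / (n_total_cycles - n_done)
  min(cap_gbq, per_cycle_ad / kidney_adaa_history[n_done])
}
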