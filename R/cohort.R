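#' Response-model specification for the synthetic cohort
#'
#' Defines how a binary radiologic response (partial response, PR) is drawn
#' from a patient's true dose metrics. Two generative forms are supported:
#'
#' * `"sigmoid_cAD"` — probability of PR as a saturating sigmoid of the
#'   cumulative absorbed dose:
#'   \eqn{P_{PR}(cAD) = P_{max} / (1 + e^{-(cAD - D_{half})/k})}.
#' * `"logistic_2d"` — logistic in both cumulative dose and the cycle-1-to-4
#'   percent change in AD/AA:
#'   \eqn{P_{PR} = 1 / (1 + e^{-(\beta_0 + \beta_1 cAD + \beta_2 \Delta)})}.
#'
#' Patients not drawn as PR are labelled stable disease (SD) or progressive
#' disease (PD) at a fixed, dose-independent ratio.
#'
#' @param kind `"sigmoid_cAD"` or `"logistic_2d"`.
#' @param pmax plateau probability of PR, percent (0-100).
#' @param dhalf cumulative dose at half of `pmax`, Gy.
#' @param k steepness scale, Gy (> 0).
#' @param beta0,beta1,beta2 logistic coefficients (intercept, per Gy, per %).
#' @param sd_pd_ratio length-2 numeric; relative odds of SD vs PD among
#'   non-responders. Default 33:12, the trial cohort's observed split.
#' @return an object of class `response_model`.
#' @export
response_model <- function(kind = c("sigmoid_cAD", "logistic_2d"),
                           pmax = 100, dhalf = 135, k = 58,
                           beta0 = NULL, beta1 = NULL, beta2 = NULL,
                           sd_pd_ratio = c(33, 12)) {
  kind <- match.arg(kind)
  if (kind == "sigmoid_cAD") {
    if (pmax < 0 || pmax > 100)
      lutadose_config_error("pmax must lie in [0, 100] percent")
    if (k <= 0) lutadose_config_error("k must be positive")
  } else {
    if (is.null(beta0) || is.null(beta1) || is.null(beta2))
      lutadose_config_error("logistic_2d requires beta0, beta1, beta2")
  }
  if (length(sd_pd_ratio) != 2 || any(sd_pd_ratio < 0) || sum(sd_pd_ratio) <= 0)
    lutadose_config_error("sd_pd_ratio must be two non-negative weights")
  structure(list(kind = kind, pmax = pmax, dhalf = dhalf, k = k,
                 beta0 = beta0, beta1 = beta1, beta2 = beta2,
                 sd_pd_ratio = sd_pd_ratio),
            class = "response_model")
}

#' Probability of partial response under a response model
#'
#' @param model a [response_model()].
#' @param cad cumulative absorbed dose, Gy.
#' @param delta_adaa percent change in AD/AA from cycle 1 to the final cycle
#'   (negative = decline); ignored by the `sigmoid_cAD` form.
#' @return probability in \[0, 1\] (vectorised).
#' @export
response_probability <- function(model, cad, delta_adaa = 0) {
  p <- switch(model$kind,
    sigmoid_cAD = (model$pmax / 100) / (1 + exp(-(cad - model$dhalf) / model$k)),
    logistic_2d = 1 / (1 + exp(-(model$beta0 + model$beta1 * cad +
                                   model$beta2 * delta_adaa))))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop(errorCondition("response model produced a probability outside [0, 1]",
                        class = c("lutadose_internal_error", "lutadose_error")))
  p
}

#' Draw a RECIST response label from a response model
#'
#' Bernoulli draw of PR at the model probability evaluated at the patient's
#' true dose metrics; non-PR patients are split SD/PD at the model's fixed
#' ratio, independent of dose.
#'
#' @inheritParams response_probability
#' @return character label, one of `"PR"`, `"SD"`, `"PD"` (vectorised).
#' @export
assign_response <- function(cad, delta_adaa, model) {
  p <- response_probability(model, cad, delta_adaa)
  n <- length(p)
  is_pr <- runif(n) < p
  p_sd <- model$sd_pd_ratio[1] / sum(model$sd_pd_ratio)
  lab <- ifelse(is_pr, "PR", ifelse(runif(n) < p_sd, "SD", "PD"))
  lab
}

#' Configuration of the synthetic dosimetry cohort
#'
#' All distributions and effect sizes used by [generate_cohort()]. The
#' defaults are calibrated so that the generated cohort reproduces the
#' statistical structure of a four-cycle 177Lu-DOTATATE dosimetry study:
#' cycle-1 tumor AD/AA with median 3.2 Gy/GBq, stable kidney AD/AA with
#' median 0.43 Gy/GBq, tumor/kidney washout half-times with medians
#' 79.5 / 47.2 h, a median multiplicative tumor-uptake decline of 10% per
#' cycle, three dose-rate samples per cycle at 4, 24 and 72 h, and a
#' kidney-dose-adaptive activity schedule (7.4 GBq first cycle, 23 Gy kidney
#' target, 11.1 GBq cap).
#'
#' Medians of positive quantities are modelled as lognormal; the `*_sigma` /
#' `*_spread` arguments are the corresponding log-scale standard deviations.
#'
#' @param n_patients number of patients.
#' @param n_cycles number of treatment cycles (>= 2).
#' @param sample_times_h dose-rate sampling times, hours, strictly increasing.
#' @param lesion_count_prob probabilities for 1..6 lesions per patient
#'   (default: 1 + Binomial(5, 0.18), mean 1.9, range 1-6).
#' @param tumor_adaa_median_c1 median cycle-1 tumor AD/AA, Gy/GBq.
#' @param tumor_adaa_sigma between-patient lognormal sigma of tumor AD/AA.
#' @param cycle_decline_median median per-cycle multiplicative change in
#'   tumor AD/AA (0.90 = 10% decline per cycle).
#' @param cycle_decline_spread lognormal sigma of the per-cycle decline draws.
#' @param kidney_adaa_median median kidney AD/AA, Gy/GBq (constant over
#'   cycles in truth).
#' @param kidney_adaa_sigma between-patient lognormal sigma of kidney AD/AA.
#' @param tumor_washout_halftime_median_h,tumor_washout_sigma median and
#'   lognormal sigma of the tumor washout half-time, h.
#' @param kidney_washout_halftime_median_h,kidney_washout_sigma same for
#'   kidneys.
#' @param uptake_halftime_h,uptake_sigma median and lognormal sigma of the
#'   uptake half-time, h.
#' @param lesion_adaa_cv lesion-level coefficient of variation around the
#'   patient-level AD/AA.
#' @param noise_cv fractional multiplicative measurement noise on each
#'   dose-rate sample.
#' @param volume_median_cm3,volume_sigma,volume_range_cm3 lognormal lesion
#'   volume distribution (cm^3), truncated to `volume_range_cm3`.
#' @param kidney_volume_cm3 nominal combined kidney volume, cm^3.
#' @param aa_schedule `"adaptive"` (kidney-dose-driven, the trial's rule) or
#'   `"fixed"` (every cycle at `first_aa_gbq`).
#' @param first_aa_gbq standardized first-cycle administered activity, GBq.
#' @param kidney_target_gy cumulative kidney absorbed-dose target, Gy.
#' @param aa_cap_gbq per-cycle administered-activity cap, GBq.
#' @param response a [response_model()]; defaults to the sigmoid-in-cAD form
#'   at Pmax 100%, Dhalf 135 Gy, k 58 Gy.
#' @param seed integer RNG seed; the cohort is a deterministic function of
#'   the configuration.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 73,
                          n_cycles = 4,
                          sample_times_h = c(4, 24, 72),
                          lesion_count_prob = stats::dbinom(0:5, 5, 0.18),
                          tumor_adaa_median_c1 = 3.2,
                          tumor_adaa_sigma = 0.6,
                          cycle_decline_median = 0.90,
                          cycle_decline_spread = 0.10,
                          kidney_adaa_median = 0.43,
                          kidney_adaa_sigma = 0.25,
                          tumor_washout_halftime_median_h = 79.5,
                          tumor_washout_sigma = 0.15,
                          kidney_washout_halftime_median_h = 47.2,
                          kidney_washout_sigma = 0.15,
                          uptake_halftime_h = 6,
                          uptake_sigma = 0,
                          lesion_adaa_cv = 0.20,
                          noise_cv = 0.10,
                          volume_median_cm3 = 28.4,
                          volume_sigma = 1.0,
                          volume_range_cm3 = c(10, 2340),
                          kidney_volume_cm3 = 300,
                          aa_schedule = c("adaptive", "fixed"),
                          first_aa_gbq = 7.4,
                          kidney_target_gy = 23,
                          aa_cap_gbq = 11.1,
                          response = response_model(),
                          seed = 1L) {
  aa_schedule <- match.arg(aa_schedule)
  cfg <- structure(as.list(environment()), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!ok) lutadose_config_error(sprintf("invalid cohort config: `%s` %s",
                                           field, what))
  }
  chk(cfg$n_patients >= 1, "n_patients", "must be >= 1")
  chk(cfg$n_cycles >= 2, "n_cycles", "must be >= 2")
  chk(all(cfg$sample_times_h > 0) && !is.unsorted(cfg$sample_times_h, strictly = TRUE),
      "sample_times_h", "must be strictly increasing and positive")
  chk(length(cfg$sample_times_h) >= 3, "sample_times_h",
      "must contain at least 3 times (3-parameter fit)")
  for (f in c("tumor_adaa_median_c1", "kidney_adaa_median",
              "tumor_washout_halftime_median_h",
              "kidney_washout_halftime_median_h", "uptake_halftime_h",
              "volume_median_cm3", "first_aa_gbq", "kidney_target_gy",
              "aa_cap_gbq"))
    chk(cfg[[f]] > 0, f, "must be positive")
  chk(cfg$cycle_decline_median > 0 && cfg$cycle_decline_median <= 1.5,
      "cycle_decline_median", "must lie in (0, 1.5]")
  chk(cfg$noise_cv >= 0, "noise_cv", "must be non-negative")
  chk(all(cfg$lesion_count_prob >= 0) && sum(cfg$lesion_count_prob) > 0,
      "lesion_count_prob", "must be non-negative weights")
  chk(inherits(cfg$response, "response_model"), "response",
      "must be a response_model object")
  invisible(cfg)
}

# Lognormal draw parameterised by its median and log-sd.
rlnorm_med <- function(n, median, sigma) {
  if (sigma == 0) return(rep(median, n))
  rlnorm(n, meanlog = log(median), sdlog = sigma)
}

#' Forward-sample noisy dose-rate measurements from true kinetics
#'
#' Evaluates the biexponential dose-rate curve at the given times and applies
#' multiplicative lognormal measurement noise with the requested coefficient
#' of variation (mean-1 noise, so measurements are unbiased in expectation).
#' SPECT quantification error scales with signal, which is why the noise is
#' multiplicative.
#'
#' @param params list with `A`, `lambda1`, `lambda2` (true curve).
#' @param times_h sampling times, hours (> 0).
#' @param noise_cv fractional coefficient of variation of the noise (>= 0).
#' @return data.frame with columns `time_h`, `doserate` (Gy/h, > 0 whenever
#'   `A > 0`).
#' @export
sample_doserates <- function(params, times_h, noise_cv) {
  if (any(times_h <= 0)) lutadose_input_error("sampling times must be positive")
  if (noise_cv < 0) lutadose_input_error("noise_cv must be non-negative")
  true <- biexp_doserate(times_h, params$A, params$lambda1, params$lambda2)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    fac <- rlnorm(length(times_h), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    fac <- 1
  }
  data.frame(time_h = times_h, doserate = true * fac)
}

# Amplitude that delivers absorbed dose `ad_gy` for given rates.
amplitude_for_dose <- function(ad_gy, lambda1, lambda2) {
  ad_gy / (1 / lambda1 - 1 / lambda2)
}

#' Generate a synthetic 177Lu-DOTATATE dosimetry cohort
#'
#' Draws a cohort of patients with per-lesion and kidney biexponential
#' kinetics, a per-cycle administered-activity schedule, noisy three-point
#' dose-rate samples for every structure and cycle, and a RECIST response
#' label drawn from the configured response model evaluated at each patient's
#' *true* cumulative tumor dose and true cycle-1-to-final percent change in
#' AD/AA. See [cohort_config()] for the generative model and its defaults.
#'
#' @param config a [cohort_config()].
#' @return an object of class `lutadose_cohort`: list with elements
#'   * `samples` — long-format data.frame (one row per dose-rate sample) with
#'     columns `patient_id`, `cycle`, `structure_id`, `structure_type`
#'     (`"tumor"`/`"kidney"`), `time_h`, `doserate_gy_per_h`, `aa_gbq`,
#'     `volume_cm3`, `response`;
#'   * `truth` — per-patient data.frame of generating values (`true_cad_gy`,
#'     `true_delta_adaa_pct`, `p_pr`, `response`, per-cycle true mean AD/AA);
#'   * `structure_truth` — per structure-cycle true kinetic parameters;
#'   * `config` — the configuration used.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  cfg <- config
  lphys <- LU177_LAMBDA_PHYS

  patients <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%04d", i)
    n_les <- sample.int(6, 1, prob = cfg$lesion_count_prob)

    # Patient-level cycle trajectory of tumor AD/AA: cycle-1 draw times
    # cumulative products of independent per-cycle decline factors.
    adaa1 <- rlnorm_med(1, cfg$tumor_adaa_median_c1, cfg$tumor_adaa_sigma)
    decline <- rlnorm_med(cfg$n_cycles - 1, cfg$cycle_decline_median,
                          cfg$cycle_decline_spread)
    adaa_c <- adaa1 * cumprod(c(1, decline))

    # mean-1 lognormal so the patient mean is centred on the patient-level
    # trajectory
    sdl <- sqrt(log(1 + cfg$lesion_adaa_cv^2))
    lesion_perturb <- rlnorm(n_les, meanlog = -sdl^2 / 2, sdlog = sdl)
    volumes <- draw_volumes(n_les, cfg)

    tumor_thalf_wash <- rlnorm_med(n_les, cfg$tumor_washout_halftime_median_h,
                                   cfg$tumor_washout_sigma)
    tumor_thalf_up <- rlnorm_med(n_les, cfg$uptake_halftime_h, cfg$uptake_sigma)

    kid_adaa <- rlnorm_med(1, cfg$kidney_adaa_median, cfg$kidney_adaa_sigma)
    kid_thalf_wash <- rlnorm_med(1, cfg$kidney_washout_halftime_median_h,
                                 cfg$kidney_washout_sigma)
    kid_thalf_up <- rlnorm_med(1, cfg$uptake_halftime_h, cfg$uptake_sigma)

    # Administered-activity schedule; the adaptive rule projects from the
    # true kidney AD/AA measured after each completed cycle.
    aa <- numeric(cfg$n_cycles)
    aa[1] <- cfg$first_aa_gbq
    if (cfg$aa_schedule == "fixed") {
      aa[] <- cfg$first_aa_gbq
    } else {
      for (cyc in seq_len(cfg$n_cycles - 1)) {
        aa[cyc + 1] <- adapt_activity(
          kidney_adaa_history = rep(kid_adaa, cyc),
          aa_history = aa[seq_len(cyc)],
          n_total_cycles = cfg$n_cycles,
          kidney_target_gy = cfg$kidney_target_gy,
          first_aa_gbq = cfg$first_aa_gbq,
          cap_gbq = cfg$aa_cap_gbq)
      }
    }

    # True patient-level metrics driving the response draw.
    mean_adaa_c <- adaa_c * mean(lesion_perturb)
    true_cad <- sum(mean_adaa_c * aa)
    true_delta <- (mean_adaa_c[cfg$n_cycles] - mean_adaa_c[1]) /
      mean_adaa_c[1] * 100

    structures <- vector("list", n_les + 1)
    for (j in seq_len(n_les)) {
      l1 <- log(2) / tumor_thalf_wash[j]
      l2 <- log(2) / tumor_thalf_up[j]
      per_cycle <- lapply(seq_len(cfg$n_cycles), function(cyc) {
        ad <- adaa_c[cyc] * lesion_perturb[j] * aa[cyc]
        A <- amplitude_for_dose(ad, l1, l2)
        s <- sample_doserates(list(A = A, lambda1 = l1, lambda2 = l2),
                              cfg$sample_times_h, cfg$noise_cv)
        list(cycle = cyc, A = A, ad_gy = ad, samples = s)
      })
      structures[[j]] <- list(structure_id = sprintf("%s_T%02d", pid, j),
                              structure_type = "tumor",
                              volume_cm3 = volumes[j],
                              lambda1 = l1, lambda2 = l2,
                              per_cycle = per_cycle)
    }
    kl1 <- log(2) / kid_thalf_wash
    kl2 <- log(2) / kid_thalf_up
    kid_cycles <- lapply(seq_len(cfg$n_cycles), function(cyc) {
      ad <- kid_adaa * aa[cyc]
      A <- amplitude_for_dose(ad, kl1, kl2)
      s <- sample_doserates(list(A = A, lambda1 = kl1, lambda2 = kl2),
                            cfg$sample_times_h, cfg$noise_cv)
      list(cycle = cyc, A = A, ad_gy = ad, samples = s)
    })
    structures[[n_les + 1]] <- list(structure_id = paste0(pid, "_K"),
                                    structure_type = "kidney",
                                    volume_cm3 = cfg$kidney_volume_cm3,
                                    lambda1 = kl1, lambda2 = kl2,
                                    per_cycle = kid_cycles)

    patients[[i]] <- list(patient_id = pid, aa_gbq = aa,
                          structures = structures,
                          true_cad_gy = true_cad,
                          true_delta_adaa_pct = true_delta,
                          true_mean_adaa = mean_adaa_c)
  }

  # Response labels drawn in one vectorised pass over patients.
  cad <- vapply(patients, `[[`, numeric(1), "true_cad_gy")
  dlt <- vapply(patients, `[[`, numeric(1), "true_delta_adaa_pct")
  p_pr <- response_probability(cfg$response, cad, dlt)
  labels <- assign_response(cad, dlt, cfg$response)

  samples <- build_sample_table(patients, labels)
  truth <- data.frame(
    patient_id = vapply(patients, `[[`, character(1), "patient_id"),
    n_lesions = vapply(patients, function(p) length(p$structures) - 1L, 1L),
    true_cad_gy = cad, true_delta_adaa_pct = dlt, p_pr = p_pr,
    response = labels, stringsAsFactors = FALSE)
  structure_truth <- build_structure_truth(patients)

  structure(list(samples = samples, truth = truth,
                 structure_truth = structure_truth, config = cfg),
            class = "lutadose_cohort")
}

draw_volumes <- function(n, cfg) {
  lo <- cfg$volume_range_cm3[1]; hi <- cfg$volume_range_cm3[2]
  v <- rlnorm_med(n, cfg$volume_median_cm3, cfg$volume_sigma)
  # resample outside the truncation range rather than clipping (no atoms at
  # the bounds)
  bad <- which(v < lo | v > hi)
  while (length(bad) > 0) {
    v[bad] <- rlnorm_med(length(bad), cfg$volume_median_cm3, cfg$volume_sigma)
    bad <- bad[v[bad] < lo | v[bad] > hi]
  }
  v
}

build_sample_table <- function(patients, labels) {
  rows <- list()
  k <- 1L
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    for (st in p$structures) {
      for (pc in st$per_cycle) {
        rows[[k]] <- data.frame(
          patient_id = p$patient_id, cycle = pc$cycle,
          structure_id = st$structure_id,
          structure_type = st$structure_type,
          time_h = pc$samples$time_h,
          doserate_gy_per_h = pc$samples$doserate,
          aa_gbq = p$aa_gbq[pc$cycle],
          volume_cm3 = st$volume_cm3,
          response = labels[i], stringsAsFactors = FALSE)
        k <- k + 1L
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

build_structure_truth <- function(patients) {
  rows <- lapply(patients, function(p) {
    do.call(rbind, lapply(p$structures, function(st) {
      data.frame(patient_id = p$patient_id,
                 structure_id = st$structure_id,
                 structure_type = st$structure_type,
                 cycle = vapply(st$per_cycle, `[[`, numeric(1), "cycle"),
                 A = vapply(st$per_cycle, `[[`, numeric(1), "A"),
                 lambda1 = st$lambda1, lambda2 = st$lambda2,
                 true_ad_gy = vapply(st$per_cycle, `[[`, numeric(1), "ad_gy"),
                 aa_gbq = p$aa_gbq[vapply(st$per_cycle, `[[`, numeric(1), "cycle")],
                 volume_cm3 = st$volume_cm3,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.lutadose_cohort <- function(x, ...) {
  cat(sprintf("Synthetic 177Lu-DOTATATE cohort: %d patients, %d cycles, %d dose-rate samples\n",
              nrow(x$truth), x$config$n_cycles, nrow(x$samples)))
  cat(sprintf("  lesions: %d; response: %s\n",
              sum(x$truth$n_lesions),
              paste(sprintf("%s=%d", names(table(x$truth$response)),
                            as.integer(table(x$truth$response))),
                    collapse = " ")))
  invisible(x)
}
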