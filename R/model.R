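# Mechanistic erythropoiesis model.
#
# Epo suppresses apoptosis of the CFU-E progenitor stage (Hill form);
# surviving progenitors amplify exponentially over a fixed proliferation
# window and enter circulation after an Epo-dependent maturation delay.
# Circulating RBCs are removed abruptly at the patient-specific life span L,
# so the steady-state count is production flux times L and the steady state
# is closed-form — which the dynamic simulator must reproduce.

#' Mechanistic model constants
#'
#' @param stem_influx Influx from the stem-cell compartment (cells/day,
#'   arbitrary scale; only the calibrated product with `hb_per_flux`
#'   matters, see [calibrate_kappa()]).
#' @param proliferation_rate Net proliferation rate over the amplification
#'   window (1/day).
#' @param apoptosis_max Maximal CFU-E apoptosis rate at zero Epo (1/day).
#' @param hill_exponent Hill exponent of the Epo dose-response (>= 1).
#' @param cfu_residence Residence time in the Epo-sensitive CFU-E stage
#'   (days).
#' @param proliferation_window Duration of the amplification window (days).
#' @param maturation_delay Baseline delay from progenitor commitment to
#'   release into circulation (days); shortened by Epo via the patient's
#'   maturation factor.
#' @param hb_per_flux Calibration constant kappa converting steady RBC count
#'   (flux x days) into hemoglobin (g/dl); `NA` until [calibrate_kappa()] is
#'   run.
#' @param epo_cap Upper bound on total Epo concentration considered by the
#'   model and solver (U/L).
#' @param hct_per_hb Fixed hematocrit/hemoglobin conversion (%/(g/dl)),
#'   the usual rule-of-three approximation.
#' @param neocytolysis List with `enabled`, `age_cutoff` (days),
#'   `epo_threshold` (U/L), `extra_rate` (1/day): when total Epo falls below
#'   the threshold, circulating cells younger than the cutoff are removed at
#'   the extra rate. Off by default.
#' @return An object of class `model_params`.
#' @export
model_params <- function(stem_influx = 1,
                         proliferation_rate = 0.7,
                         apoptosis_max = 0.35,
                         hill_exponent = 2,
                         cfu_residence = 6,
                         proliferation_window = 5,
                         maturation_delay = 3,
                         hb_per_flux = NA_real_,
                         epo_cap = 10000,
                         hct_per_hb = 3.0,
                         neocytolysis = list(enabled = FALSE,
                                             age_cutoff = 14,
                                             epo_threshold = 10,
                                             extra_rate = 0.05)) {
  stopifnot(stem_influx > 0, proliferation_rate >= 0, apoptosis_max >= 0,
            hill_exponent >= 1, cfu_residence >= 0,
            proliferation_window >= 0, maturation_delay >= 0, epo_cap > 0,
            hct_per_hb > 0)
  neo <- utils::modifyList(list(enabled = FALSE, age_cutoff = 14,
                                epo_threshold = 10, extra_rate = 0.05),
                           neocytolysis)
  stopifnot(neo$age_cutoff >= 0, neo$epo_threshold >= 0, neo$extra_rate >= 0)
  structure(list(stem_influx = stem_influx,
                 proliferation_rate = proliferation_rate,
                 apoptosis_max = apoptosis_max,
                 hill_exponent = hill_exponent,
                 cfu_residence = cfu_residence,
                 proliferation_window = proliferation_window,
                 maturation_delay = maturation_delay,
                 hb_per_flux = hb_per_flux,
                 epo_cap = epo_cap,
                 hct_per_hb = hct_per_hb,
                 neocytolysis = neo),
            class = "model_params")
}

# Accept either a one-row population data.frame or a plain list with the
# same fields; returns a list with short names.
as_patient <- function(patient) {
  if (is.data.frame(patient)) {
    stopifnot(nrow(patient) == 1)
    list(L = patient$rbc_life_span_days,
         epo0 = patient$endogenous_epo_u_per_l,
         theta = patient$apoptosis_sensitivity_u_per_l,
         mf = patient$maturation_factor)
  } else {
    list(L = patient$rbc_life_span_days %||% patient$L,
         epo0 = patient$endogenous_epo_u_per_l %||% patient$epo0,
         theta = patient$apoptosis_sensitivity_u_per_l %||% patient$theta,
         mf = patient$maturation_factor %||% patient$mf)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' CFU-E apoptosis rate as a function of total Epo
#'
#' Hill-type suppression: `alpha(E) = alpha_max * theta^h / (theta^h + E^h)`
#' with `theta` the patient's half-effect Epo concentration. Strictly
#' decreasing in `E`; equals `alpha_max` at `E = 0` and `alpha_max / 2` at
#' `E = theta`.
#'
#' @param epo_total Total Epo concentration (U/L), vectorized, >= 0.
#' @param patient Patient parameters ([patient_params()] row).
#' @param model [model_params()].
#' @return Apoptosis rate(s) in 1/day.
#' @export
apoptosis_rate <- function(epo_total, patient, model) {
  if (any(epo_total < 0)) stop("`epo_total` must be non-negative")
  p <- as_patient(patient)
  h <- model$hill_exponent
  model$apoptosis_max * p$theta^h / (p$theta^h + epo_total^h)
}

#' Steady production flux of RBCs into circulation
#'
#' `P(E) = S0 * exp(beta * tau_p - alpha(E) * tau_CFU)`: exponential
#' amplification over the proliferation window, attenuated by apoptosis
#' during CFU-E residence. Strictly increasing in Epo.
#'
#' @inheritParams apoptosis_rate
#' @return Production flux (cells/day, arbitrary scale), vectorized.
#' @export
production_flux <- function(epo_total, patient, model) {
  a <- apoptosis_rate(epo_total, patient, model)
  model$stem_influx *
    exp(model$proliferation_rate * model$proliferation_window -
          a * model$cfu_residence)
}

#' Analytic steady state at constant total Epo
#'
#' With abrupt removal at age `L`, the steady-state circulating count is
#' `P(E) * L` and hemoglobin is `kappa * P(E) * L`. Requires a calibrated
#' model (see [calibrate_kappa()]).
#'
#' @inheritParams apoptosis_rate
#' @param epo_total Total Epo concentration (U/L), scalar in
#'   `[0, epo_cap]`.
#' @return An object of class `steady_state`: list with `epo_total`,
#'   `production_flux`, `rbc_count`, `hemoglobin` (g/dl), `hematocrit` (%).
#' @export
steady_state <- function(epo_total, patient, model) {
  if (is.na(model$hb_per_flux))
    stop("model is uncalibrated; run calibrate_kappa() first")
  if (any(epo_total > model$epo_cap))
    stop("`epo_total` exceeds the model's Epo cap")
  p <- as_patient(patient)
  flux <- production_flux(epo_total, patient, model)
  count <- flux * p$L
  hb <- model$hb_per_flux * count
  structure(list(epo_total = epo_total,
                 production_flux = flux,
                 rbc_count = count,
                 hemoglobin = hb,
                 hematocrit = model$hct_per_hb * hb),
            class = "steady_state")
}

# Vectorized steady-state hemoglobin over an Epo grid (internal fast path
# for the requirement solver and the grid-search oracle).
steady_hb <- function(epo_total, patient, model) {
  p <- as_patient(patient)
  model$hb_per_flux * production_flux(epo_total, patient, model) * p$L
}

#' Calibrate the hemoglobin scale constant
#'
#' Sets `hb_per_flux` (kappa) so that a reference patient with the given
#' life span, held at the given constant total Epo, sits exactly at the
#' reference hemoglobin. The default anchor -- healthy life span 120 days at
#' the cohort-median Epo 15 U/L giving 14.0 g/dl -- makes a
#' healthy-physiology patient normo-hemic. Since kappa multiplies the flux,
#' the pair (stem_influx, kappa) only enters through its product: rescaling
#' `stem_influx` and recalibrating leaves every hemoglobin unchanged.
#'
#' @param model [model_params()] to calibrate.
#' @param reference_life_span RBC life span of the anchor patient (days).
#' @param reference_epo Constant total Epo of the anchor (U/L).
#' @param reference_hb Target hemoglobin of the anchor (g/dl).
#' @return The model with `hb_per_flux` set.
#' @export
calibrate_kappa <- function(model, reference_life_span = 120,
                            reference_epo = 15, reference_hb = 14.0) {
  stopifnot(reference_life_span > 0, reference_epo > 0, reference_hb > 0)
  ref <- patient_params(rbc_life_span = reference_life_span,
                        endogenous_epo = reference_epo)
  flux <- production_flux(reference_epo, ref, model)
  if (!is.finite(flux) || flux <= 0)
    stop("calibration failed: zero or non-finite production flux at the ",
         "reference point")
  model$hb_per_flux <- reference_hb / (flux * reference_life_span)
  model
}

#' ESA concentration from a dosing schedule
#'
#' Superposition of one-compartment exponential decays: each administration
#' contributes `increment * 2^(-(t - t_i) * 24 / half_life_hours)` for
#' `t >= t_i`.
#'
#' @param schedule An [esa_schedule()].
#' @param t Time(s) in days, >= 0; vectorized.
#' @return Concentration(s) in U/L.
#' @export
esa_concentration <- function(schedule, t) {
  stopifnot(inherits(schedule, "esa_schedule"))
  rate <- log(2) * 24 / schedule$half_life
  vapply(t, function(tt) {
    i <- schedule$times <= tt
    sum(schedule$increments[i] * exp(-rate * (tt - schedule$times[i])))
  }, numeric(1))
}

#' ESA administration schedule
#'
#' @param times Administration times (days), non-decreasing.
#' @param increments Concentration increments per administration (U/L),
#'   >= 0, same length as `times`.
#' @param half_life ESA elimination half-life (hours).
#' @return An object of class `esa_schedule`.
#' @export
esa_schedule <- function(times = numeric(), increments = numeric(),
                         half_life = 20) {
  stopifnot(length(times) == length(increments), half_life > 0)
  if (is.unsorted(times)) stop("`times` must be non-decreasing")
  if (any(increments < 0)) stop("`increments` must be non-negative")
  structure(list(times = times, increments = increments,
                 half_life = half_life),
            class = "esa_schedule")
}

#' Dynamic age-structured simulation of the circulating RBC pool
#'
#' Discretizes cell age on a uniform grid of spacing `dt`. Each step a
#' cohort of size `P(E(t - tau_d)) * dt` enters circulation, where the
#' maturation delay `tau_d(E) = tau_d0 / (1 + mf * E / (E + theta))`
#' shortens with Epo. Cohorts are removed abruptly at age `L` (the cohort
#' straddling `L` is removed pro rata, so the steady count is exactly
#' `P * L`). Optionally, neocytolysis removes cohorts younger than the age
#' cutoff at an extra exponential rate whenever total Epo is below the
#' threshold.
#'
#' @param patient Patient parameters ([patient_params()] row).
#' @param model Calibrated [model_params()].
#' @param epo_of_t Function mapping time (days) to total Epo (U/L).
#' @param t_end Simulation horizon (days), > 0.
#' @param dt Time and age step (days), > 0.
#' @param neocytolysis Override the model's neocytolysis `enabled` flag.
#' @return A `data.frame` of class `trajectory` with columns `time_days`,
#'   `hemoglobin_g_dl`, `epo_u_per_l`, `flux`. The attribute
#'   `conservation_error` holds the maximum absolute per-step imbalance of
#'   (entering - removed - change in count), relative to the count.
#' @export
simulate_rbc <- function(patient, model, epo_of_t, t_end, dt = 0.25,
                         neocytolysis = model$neocytolysis$enabled) {
  if (dt <= 0) stop("`dt` must be positive")
  if (t_end <= 0) stop("`t_end` must be positive")
  if (is.na(model$hb_per_flux))
    stop("model is uncalibrated; run calibrate_kappa() first")
  p <- as_patient(patient)
  L <- p$L
  neo <- model$neocytolysis
  n_steps <- ceiling(t_end / dt)
  n_age <- max(ceiling(L / dt) + 2L, 2L)
  ages_lo <- (seq_len(n_age) - 1) * dt
  # fraction of a cohort in age bucket k that has not yet hit age L
  w <- pmin(1, pmax(0, (L - ages_lo) / dt))
  w_next <- c(w[-1], 0)
  young <- ages_lo < neo$age_cutoff
  neo_decay <- exp(-neo$extra_rate * dt)

  orig <- numeric(n_age)  # cohort sizes before age attrition (orig * w = alive)
  count <- 0
  times <- seq_len(n_steps) * dt
  hb <- epo <- flux <- numeric(n_steps)
  max_imbalance <- 0

  for (i in seq_len(n_steps)) {
    t_now <- times[i] - dt
    e_now <- epo_of_t(t_now)
    if (e_now < 0) stop("`epo_of_t` returned a negative concentration")
    tau_d <- model$maturation_delay /
      (1 + p$mf * e_now / (e_now + p$theta))
    e_lag <- epo_of_t(max(t_now - tau_d, 0))
    influx <- production_flux(e_lag, patient, model) * dt

    removed_neo <- 0
    if (neocytolysis && e_now < neo$epo_threshold) {
      alive_young <- sum(orig[young] * w[young])
      orig[young] <- orig[young] * neo_decay
      removed_neo <- alive_young * (1 - neo_decay)
    }
    # ageing: every cohort moves one bucket up; the part of each cohort that
    # crosses age L is removed
    removed_age <- sum(orig * (w - w_next)) + influx * (1 - w[1])
    orig <- c(influx, orig[-n_age])
    new_count <- sum(orig * w)

    imbalance <- abs((new_count - count) - (influx - removed_age -
                                              removed_neo))
    max_imbalance <- max(max_imbalance,
                         imbalance / max(new_count, .Machine$double.eps))
    count <- new_count
    hb[i] <- model$hb_per_flux * count
    epo[i] <- e_now
    flux[i] <- influx / dt
  }

  traj <- data.frame(time_days = times, hemoglobin_g_dl = hb,
                     epo_u_per_l = epo, flux = flux)
  class(traj) <- c("trajectory", "data.frame")
  attr(traj, "conservation_error") <- max_imbalance
  traj
}

#' @export
print.model_params <- function(x, ...) {
  cat("Erythropoiesis model parameters\n")
  cat(sprintf("  amplification: exp(beta*tau_p) = exp(%.2f * %.1f)\n",
              x$proliferation_rate, x$proliferation_window))
  cat(sprintf("  apoptosis: alpha_max %.2f/d over tau_CFU %.1f d, Hill h = %g\n",
              x$apoptosis_max, x$cfu_residence, x$hill_exponent))
  cat(sprintf("  maturation delay tau_d0 = %.1f d; Epo cap %g U/L\n",
              x$maturation_delay, x$epo_cap))
  cat(sprintf("  kappa (hb per flux*days): %s\n",
              if (is.na(x$hb_per_flux)) "uncalibrated"
              else format(x$hb_per_flux, digits = 6)))
  cat(sprintf("  neocytolysis: %s\n",
              if (x$neocytolysis$enabled) "enabled" else "disabled"))
  invisible(x)
}
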