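# Phenomenological single-variable hematocrit model: ESA administrations
# raise hematocrit through an effective production rate, and the produced
# hematocrit persists according to a survival kernel set by RBC life span
# and its variability. No bone-marrow stages are resolved.

#' Phenomenological model parameters
#'
#' @param baseline_production Hematocrit production at zero ESA (%/day).
#' @param esa_efficacy Extra hematocrit production per unit of ESA
#'   concentration above threshold (%/day per U/L).
#' @param esa_threshold Concentration threshold for ESA response (U/L);
#'   concentrations at or below it have no effect.
#' @param life_span RBC life span L (days), > 0.
#' @param life_span_spread Spread of the survival kernel around L (days);
#'   0 gives rectangular (abrupt) survival.
#' @return An object of class `pheno_params`.
#' @export
pheno_params <- function(baseline_production = 0.3, esa_efficacy = 0.01,
                         esa_threshold = 5, life_span = 76,
                         life_span_spread = 0) {
  stopifnot(baseline_production >= 0, esa_efficacy >= 0, esa_threshold >= 0,
            life_span > 0, life_span_spread >= 0)
  structure(list(baseline_production = baseline_production,
                 esa_efficacy = esa_efficacy,
                 esa_threshold = esa_threshold,
                 life_span = life_span,
                 life_span_spread = life_span_spread),
            class = "pheno_params")
}

#' Effective hematocrit production rate at a given ESA concentration
#'
#' Linear above threshold:
#' `p(C) = p0 + efficacy * max(0, C - threshold)`.
#'
#' @param concentration ESA concentration(s) in U/L, >= 0.
#' @param params [pheno_params()].
#' @return Production rate(s) in %/day.
#' @export
production_rate <- function(concentration, params) {
  if (any(concentration < 0)) stop("`concentration` must be non-negative")
  params$baseline_production +
    params$esa_efficacy * pmax(0, concentration - params$esa_threshold)
}

#' Survival fraction of hematocrit produced `age` days ago
#'
#' Logistic kernel `S(a) = 1 / (1 + exp((a - L) / s_L))` for spread
#' `s_L > 0`; for `s_L = 0` the pointwise limit: 1 for `a < L`, 1/2 at
#' `a = L`, 0 beyond (the midpoint value keeps trapezoid quadrature of the
#' rectangular kernel exact). Integrates to L (within ~exp(-L/s_L)) so the
#' steady hematocrit under constant production p is p * L.
#'
#' @param age Age(s) in days, >= 0.
#' @param params [pheno_params()].
#' @return Fraction(s) in \[0, 1\].
#' @export
survival_fraction <- function(age, params) {
  if (any(age < 0)) stop("`age` must be non-negative")
  if (params$life_span_spread == 0) {
    ifelse(age < params$life_span, 1,
           ifelse(age == params$life_span, 0.5, 0))
  } else {
    stats::plogis((params$life_span - age) / params$life_span_spread)
  }
}

#' Hematocrit trajectory under an ESA schedule
#'
#' Convolution of production with the survival kernel,
#' `H(t) = integral_0^t p(C(s)) S(t - s) ds`, evaluated by the trapezoid
#' rule on the `dt` grid starting from an empty circulation. Read steady
#' values only after a burn-in of about 5 * L days.
#'
#' @param schedule An [esa_schedule()] (use an empty one for
#'   endogenous-only runs).
#' @param params [pheno_params()].
#' @param t_end Horizon (days).
#' @param dt Grid step (days), > 0.
#' @return A `data.frame` of class `trajectory` with columns `time_days`,
#'   `hematocrit_pct`, `esa_u_per_l`, `production_pct_per_day`.
#' @export
hematocrit_trajectory <- function(schedule, params, t_end, dt = 0.25) {
  if (dt <= 0) stop("`dt` must be positive")
  tt <- seq(0, t_end, by = dt)
  n <- length(tt)
  conc <- esa_concentration(schedule, tt)
  p <- production_rate(conc, params)
  s <- survival_fraction(tt, params)
  # open convolution cv[k] = sum_{i+j=k+1} p[i] s[j]; trapezoid corrects the
  # two endpoint weights
  cv <- stats::convolve(p, rev(s), type = "open")[seq_len(n)]
  h <- dt * (cv - 0.5 * p[1] * s - 0.5 * p * s[1])
  h[1] <- 0
  h <- pmax(h, 0)
  traj <- data.frame(time_days = tt, hematocrit_pct = h,
                     esa_u_per_l = conc, production_pct_per_day = p)
  class(traj) <- c("trajectory", "data.frame")
  traj
}
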