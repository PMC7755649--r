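# Virtual patient population generator.
#
# Each virtual patient ("anemia avatar") is an erythropoiesis-related
# parameter set: RBC life span, endogenous Epo level, ESA half-life, the
# half-effect Epo concentration for apoptosis suppression, and a maturation
# velocity factor. Life spans follow a truncated normal calibrated so the
# post-truncation mean/SD hit stated targets; the remaining parameters are
# lognormal.

#' Truncated-normal generator specification
#'
#' Describes a normal distribution with the given `location` and `scale`
#' truncated to `[lower, upper]`. Note that `location` and `scale` are the
#' parameters of the parent normal, not the post-truncation mean and SD;
#' use [fit_truncated_normal()] to calibrate them to target moments.
#'
#' @param location Location (days) of the parent normal.
#' @param scale Scale (days) of the parent normal; must be positive.
#' @param lower,upper Truncation bounds (days), `lower < upper`.
#' @return An object of class `trunc_norm_spec`.
#' @seealso [fit_truncated_normal()], [sample_population()]
#' @export
trunc_norm_spec <- function(location, scale, lower, upper) {
  stopifnot(is.numeric(location), is.numeric(scale), is.numeric(lower),
            is.numeric(upper))
  if (scale <= 0) stop("`scale` must be positive")
  if (lower >= upper) stop("`lower` must be strictly less than `upper`")
  structure(list(location = location, scale = scale,
                 lower = lower, upper = upper),
            class = "trunc_norm_spec")
}

#' Lognormal generator specification
#'
#' @param log_median Natural log of the distribution median.
#' @param log_sd Standard deviation on the log scale; must be positive.
#' @return An object of class `lognorm_spec`.
#' @export
lognorm_spec <- function(log_median, log_sd) {
  stopifnot(is.numeric(log_median), is.numeric(log_sd))
  if (log_sd <= 0) stop("`log_sd` must be positive")
  structure(list(log_median = log_median, log_sd = log_sd),
            class = "lognorm_spec")
}

# Mean and SD of a normal(location, scale) truncated to [lower, upper],
# via the standard phi/Phi expressions.
tnorm_moments <- function(location, scale, lower, upper) {
  a <- (lower - location) / scale
  b <- (upper - location) / scale
  z <- stats::pnorm(b) - stats::pnorm(a)
  if (z <= 0) return(list(mean = NaN, sd = NaN))
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  r <- (da - db) / z
  m <- location + scale * r
  # a*dnorm(a) -> 0 as a -> -Inf; guard the products for infinite bounds
  ada <- if (is.finite(a)) a * da else 0
  bdb <- if (is.finite(b)) b * db else 0
  v <- scale^2 * (1 + (ada - bdb) / z - r^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

#' Calibrate a truncated normal to post-truncation moments
#'
#' Solves for the `(location, scale)` of a parent normal such that, after
#' truncation to `[lower, upper]`, the distribution has the requested mean
#' and standard deviation. Naively truncating a normal with the target
#' moments would not work: an asymmetric truncation range shifts the
#' post-truncation mean away from the parent location.
#'
#' @param target_mean Desired post-truncation mean (days).
#' @param target_sd Desired post-truncation SD (days); positive.
#' @param lower,upper Truncation bounds (days); must straddle `target_mean`.
#' @param tol Relative tolerance on both recovered moments (default `1e-6`).
#' @return A [trunc_norm_spec()] whose truncated mean/SD match the targets.
#' @examples
#' spec <- fit_truncated_normal(76, 21, 33, 137)
#' @export
fit_truncated_normal <- function(target_mean, target_sd, lower, upper,
                                 tol = 1e-6) {
  if (!(lower < target_mean && target_mean < upper))
    stop("`target_mean` must lie strictly inside [lower, upper]")
  if (target_sd <= 0) stop("`target_sd` must be positive")

  resid <- function(par) {
    m <- tnorm_moments(par[1], exp(par[2]), lower, upper)
    c((m$mean - target_mean) / target_sd, (m$sd - target_sd) / target_sd)
  }
  obj <- function(par) sum(resid(par)^2)

  par <- c(target_mean, log(target_sd))
  scale_ref <- max(abs(target_mean), target_sd)
  ok <- function(par) {
    m <- tnorm_moments(par[1], exp(par[2]), lower, upper)
    is.finite(m$mean) && is.finite(m$sd) &&
      abs(m$mean - target_mean) <= tol * scale_ref &&
      abs(m$sd - target_sd) <= tol * scale_ref
  }
  if (!ok(par)) {
    for (method in c("BFGS", "Nelder-Mead")) {
      fit <- stats::optim(par, obj, method = method,
                          control = list(maxit = 2000, reltol = 1e-16,
                                         abstol = 1e-18))
      par <- fit$par
      if (ok(par)) break
    }
  }
  if (!ok(par))
    stop("truncated-normal calibration failed to reach the requested ",
         "moments within tolerance")
  trunc_norm_spec(par[1], exp(par[2]), lower, upper)
}

#' Fit a lognormal from a median and quartiles
#'
#' The log-median is taken exactly as `log(median)`; the log-scale SD is the
#' least-squares solution of the two log-quartile equations,
#' `log_sd = (log(median/q25) + log(q75/median)) / (2 * z75)` with `z75` the
#' standard-normal 75th percentile. When the printed quartiles are not
#' exactly lognormal-consistent this averages the two implied sigmas.
#'
#' @param median Distribution median (must exceed `q25`).
#' @param q25,q75 The 25th and 75th percentiles, `0 < q25 < median < q75`.
#' @return A [lognorm_spec()].
#' @examples
#' fit_lognormal_from_quantiles(15, 10.2, 21.1)
#' @export
fit_lognormal_from_quantiles <- function(median, q25, q75) {
  if (!(0 < q25 && q25 < median && median < q75))
    stop("quantiles must satisfy 0 < q25 < median < q75")
  z75 <- stats::qnorm(0.75)
  log_sd <- (log(median / q25) + log(q75 / median)) / (2 * z75)
  lognorm_spec(log(median), log_sd)
}

# Inverse-CDF sampling restricted to [lower, upper]: no rejection, no
# out-of-range values.
sample_trunc_norm <- function(n, spec) {
  p_lo <- stats::pnorm(spec$lower, spec$location, spec$scale)
  p_hi <- stats::pnorm(spec$upper, spec$location, spec$scale)
  u <- stats::runif(n, p_lo, p_hi)
  x <- stats::qnorm(u, spec$location, spec$scale)
  pmin(pmax(x, spec$lower), spec$upper)
}

sample_lognorm <- function(n, spec) {
  stats::rlnorm(n, meanlog = spec$log_median, sdlog = spec$log_sd)
}

#' Default generator specs for the virtual population
#'
#' Life spans: truncated normal calibrated so the post-truncation mean/SD
#' are 76/21 days on \[33, 137\] days. Endogenous Epo: lognormal fitted to
#' median 15 U/L with quartiles 10.2 and 21.1 U/L. The remaining patient
#' parameters are not reported at the population level; defaults are
#' lognormals around plausible central values (ESA half-life median 20 h,
#' apoptosis half-effect Epo 30 U/L, maturation factor 0.5) whose spread
#' produces realistic within-bin heterogeneity. All are overridable.
#'
#' @param life_span_mean,life_span_sd,life_span_min,life_span_max
#'   Post-truncation moments and hard range for RBC life spans (days).
#' @param epo_median,epo_q25,epo_q75 Endogenous Epo median and quartiles (U/L).
#' @param esa_half_life,apoptosis_sensitivity,maturation_factor
#'   [lognorm_spec()] objects for the unreported parameters.
#' @return Named list of generator specs, one per patient parameter.
#' @export
default_population_specs <- function(life_span_mean = 76, life_span_sd = 21,
                                     life_span_min = 33, life_span_max = 137,
                                     epo_median = 15, epo_q25 = 10.2,
                                     epo_q75 = 21.1,
                                     esa_half_life =
                                       lognorm_spec(log(20), 0.3),
                                     apoptosis_sensitivity =
                                       lognorm_spec(log(30), 0.4),
                                     maturation_factor =
                                       lognorm_spec(log(0.5), 0.4)) {
  list(
    rbc_life_span = fit_truncated_normal(life_span_mean, life_span_sd,
                                         life_span_min, life_span_max),
    endogenous_epo = fit_lognormal_from_quantiles(epo_median, epo_q25,
                                                  epo_q75),
    esa_half_life = esa_half_life,
    apoptosis_sensitivity = apoptosis_sensitivity,
    maturation_factor = maturation_factor
  )
}

# Per-field substream seeds derived from the root seed, so adding or
# reordering a field never perturbs another field's draws.
field_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483647 + offset * 1000003) %% 2147483647)
}

#' Sample a virtual patient population
#'
#' Draws `n` independent virtual patients from the generator specs. Each
#' parameter uses its own RNG substream derived from the root seed, so the
#' result is reproducible bit-for-bit for a given `(n, specs, seed)` and
#' individual parameter columns do not depend on the presence of others.
#'
#' @param n Number of patients (>= 1).
#' @param specs Generator specs as returned by [default_population_specs()].
#' @param seed Integer root seed.
#' @return A `data.frame` with columns `patient_id`, `rbc_life_span_days`,
#'   `endogenous_epo_u_per_l`, `esa_half_life_h`,
#'   `apoptosis_sensitivity_u_per_l`, `maturation_factor`; attributes
#'   `seed` and `specs` record the generation inputs.
#' @examples
#' pop <- sample_population(100, seed = 1)
#' range(pop$rbc_life_span_days)
#' @export
sample_population <- function(n, specs = default_population_specs(),
                              seed = 1L) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("`n` must be a single integer >= 1")
  n <- as.integer(n)
  offsets <- c(rbc_life_span = 101, endogenous_epo = 211,
               esa_half_life = 307, apoptosis_sensitivity = 401,
               maturation_factor = 503)
  draw <- function(field) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(field_seed(seed, offsets[[field]]))
    spec <- specs[[field]]
    if (inherits(spec, "trunc_norm_spec")) sample_trunc_norm(n, spec)
    else sample_lognorm(n, spec)
  }
  pop <- data.frame(
    patient_id = seq_len(n),
    rbc_life_span_days = draw("rbc_life_span"),
    endogenous_epo_u_per_l = draw("endogenous_epo"),
    esa_half_life_h = draw("esa_half_life"),
    apoptosis_sensitivity_u_per_l = draw("apoptosis_sensitivity"),
    maturation_factor = draw("maturation_factor")
  )
  attr(pop, "seed") <- as.integer(seed)
  attr(pop, "specs") <- specs
  pop
}

#' Single virtual patient constructor
#'
#' Convenience constructor for one patient parameter set, mainly for
#' calibration anchors and targeted comparisons (e.g. two patients identical
#' except for life span).
#'
#' @param rbc_life_span RBC life span (days), age at which circulating cells
#'   are removed.
#' @param endogenous_epo Endogenous Epo level (U/L).
#' @param esa_half_life ESA elimination half-life (hours).
#' @param apoptosis_sensitivity Half-effect Epo concentration for CFU-E
#'   apoptosis suppression (U/L).
#' @param maturation_factor Dimensionless strength of the Epo effect on
#'   maturation velocity (>= 0).
#' @param patient_id Integer identifier.
#' @return A one-row `data.frame` with the population column layout.
#' @export
patient_params <- function(rbc_life_span, endogenous_epo = 15,
                           esa_half_life = 20, apoptosis_sensitivity = 30,
                           maturation_factor = 0.5, patient_id = 1L) {
  if (rbc_life_span < 0) stop("`rbc_life_span` must be non-negative")
  if (endogenous_epo <= 0) stop("`endogenous_epo` must be positive")
  if (esa_half_life <= 0) stop("`esa_half_life` must be positive")
  if (apoptosis_sensitivity <= 0)
    stop("`apoptosis_sensitivity` must be positive")
  if (maturation_factor < 0) stop("`maturation_factor` must be >= 0")
  data.frame(
    patient_id = as.integer(patient_id),
    rbc_life_span_days = rbc_life_span,
    endogenous_epo_u_per_l = endogenous_epo,
    esa_half_life_h = esa_half_life,
    apoptosis_sensitivity_u_per_l = apoptosis_sensitivity,
    maturation_factor = maturation_factor
  )
}
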