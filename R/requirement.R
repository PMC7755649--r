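# Per-patient required-Epo solver and the binned population summaries:
# box-plot statistics of required Epo per 10-day life-span bin, and mean
# required increase over endogenous Epo on a (life span x endogenous Epo)
# grid.

#' Analysis configuration
#'
#' @param hb_lo,hb_hi Hemoglobin target window (g/dl); the solver aims at
#'   the midpoint and declares convergence on window membership.
#' @param lifespan_bin_width Width of the RBC life-span bins (days), aligned
#'   to multiples of the width.
#' @param epo_bin_start,epo_bin_width First edge and width of the endogenous
#'   Epo bins (U/L); defaults give edges 5, 15, 25, ...
#' @param min_cell_count Minimum patients per (life span x Epo) cell for the
#'   cell to be included in the density grid.
#' @param clamp_negative_delta If `TRUE`, the grid uses
#'   `max(0, required - endogenous)`; the raw difference is always retained
#'   in the per-patient results.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(hb_lo = 10.49, hb_hi = 10.51,
                            lifespan_bin_width = 10,
                            epo_bin_start = 5, epo_bin_width = 10,
                            min_cell_count = 25,
                            clamp_negative_delta = TRUE) {
  stopifnot(hb_lo < hb_hi, lifespan_bin_width > 0, epo_bin_width > 0,
            min_cell_count >= 1)
  structure(list(hb_lo = hb_lo, hb_hi = hb_hi,
                 lifespan_bin_width = lifespan_bin_width,
                 epo_bin_start = epo_bin_start,
                 epo_bin_width = epo_bin_width,
                 min_cell_count = min_cell_count,
                 clamp_negative_delta = clamp_negative_delta),
            class = "analysis_config")
}

#' Required total Epo for one patient
#'
#' Finds the constant total Epo concentration E* at which the patient's
#' steady-state hemoglobin equals the midpoint of the target window, by
#' bracket doubling from \[0, 1\] followed by Brent root finding
#' ([stats::uniroot()]). Steady hemoglobin is strictly increasing in Epo,
#' so the root is unique. Patients whose hemoglobin at the Epo cap still
#' falls short of the window are returned as non-achievers
#' (`converged = FALSE`, `required_total_epo = epo_cap`); a patient already
#' above the window at zero Epo is likewise non-converged with requirement
#' 0.
#'
#' @param patient Patient parameters ([patient_params()] row).
#' @param model Calibrated [model_params()].
#' @param cfg [analysis_config()].
#' @return A list of class `required_epo`: `patient_id`,
#'   `required_total_epo`, `delta_raw` (required - endogenous),
#'   `delta_clamped`, `achieved_hb`, `converged`, `iterations`.
#' @export
required_total_epo <- function(patient, model, cfg = analysis_config()) {
  if (is.na(model$hb_per_flux))
    stop("model is uncalibrated; run calibrate_kappa() first")
  p <- as_patient(patient)
  target <- (cfg$hb_lo + cfg$hb_hi) / 2
  evals <- 0L
  hb_at <- function(e) {
    evals <<- evals + 1L
    h <- steady_hb(e, patient, model)
    if (!is.finite(h)) stop("non-finite hemoglobin at Epo = ", e)
    h
  }

  finish <- function(e_star, achieved) {
    delta <- e_star - p$epo0
    structure(list(
      patient_id = patient$patient_id %||% 1L,
      required_total_epo = e_star,
      delta_raw = delta,
      delta_clamped = max(0, delta),
      achieved_hb = achieved,
      converged = achieved >= cfg$hb_lo && achieved <= cfg$hb_hi,
      iterations = evals), class = "required_epo")
  }

  hb0 <- hb_at(0)
  if (hb0 >= target) return(finish(0, hb0))

  e_hi <- 1
  while (hb_at(e_hi) < target && e_hi < model$epo_cap)
    e_hi <- min(2 * e_hi, model$epo_cap)
  if (hb_at(e_hi) < target) {
    # target out of reach below the cap
    return(finish(model$epo_cap, hb_at(model$epo_cap)))
  }
  root <- stats::uniroot(function(e) hb_at(e) - target,
                         lower = 0, upper = e_hi,
                         tol = 1e-10 * max(1, e_hi))
  finish(root$root, hb_at(root$root))
}

#' Solve the required Epo for every patient in a population
#'
#' @param population Population table from [sample_population()].
#' @param model Calibrated [model_params()].
#' @param cfg [analysis_config()].
#' @return A `data.frame` with one row per patient: the population columns
#'   `patient_id`, `rbc_life_span_days`, `endogenous_epo_u_per_l` plus
#'   `required_total_epo_u_per_l`, `delta_raw_u_per_l`,
#'   `delta_clamped_u_per_l`, `achieved_hb_g_dl`, `converged`, `iterations`.
#' @export
solve_population <- function(population, model, cfg = analysis_config()) {
  stopifnot(is.data.frame(population), nrow(population) >= 1)
  n <- nrow(population)
  req <- draw <- dclamp <- hb <- numeric(n)
  conv <- logical(n)
  iters <- integer(n)
  for (i in seq_len(n)) {
    pat <- list(patient_id = population$patient_id[i],
                rbc_life_span_days = population$rbc_life_span_days[i],
                endogenous_epo_u_per_l = population$endogenous_epo_u_per_l[i],
                apoptosis_sensitivity_u_per_l =
                  population$apoptosis_sensitivity_u_per_l[i],
                maturation_factor = population$maturation_factor[i])
    r <- required_total_epo(pat, model, cfg)
    req[i] <- r$required_total_epo
    draw[i] <- r$delta_raw
    dclamp[i] <- r$delta_clamped
    hb[i] <- r$achieved_hb
    conv[i] <- r$converged
    iters[i] <- r$iterations
  }
  data.frame(patient_id = population$patient_id,
             rbc_life_span_days = population$rbc_life_span_days,
             endogenous_epo_u_per_l = population$endogenous_epo_u_per_l,
             required_total_epo_u_per_l = req,
             delta_raw_u_per_l = draw,
             delta_clamped_u_per_l = dclamp,
             achieved_hb_g_dl = hb,
             converged = conv,
             iterations = iters)
}

#' Box-plot statistics with 1.5 IQR outlier fences
#'
#' Quartiles by linear interpolation of order statistics
#' ([stats::quantile()] type 7). Whiskers are the most extreme values still
#' inside `[q1 - 1.5 IQR, q3 + 1.5 IQR]`; values beyond the fences are
#' counted as outliers.
#'
#' @param values Non-empty numeric vector.
#' @return Named list: `n`, `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`, `n_outliers`.
#' @export
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("`values` must be non-empty")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(n = length(values),
       median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(values[inside]),
       whisker_hi = max(values[inside]),
       n_outliers = sum(!inside))
}

lifespan_bin_lo <- function(L, width) floor(L / width) * width

#' Box-plot summaries of required Epo per life-span bin
#'
#' Converged patients are grouped into half-open life-span bins
#' `[lo, lo + width)` aligned to multiples of the bin width, and
#' [boxplot_stats()] of their required total Epo is reported per non-empty
#' bin. Non-achievers are excluded.
#'
#' @param results Output of [solve_population()].
#' @param cfg [analysis_config()].
#' @param column Which quantity to summarize: total required Epo
#'   (`"required_total_epo_u_per_l"`, default) or the increase over
#'   endogenous (`"delta_raw_u_per_l"` / `"delta_clamped_u_per_l"`).
#' @return A `data.frame` with columns `bin_lo_days`, `bin_hi_days`, `n`,
#'   `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`, `n_outliers`,
#'   ordered by bin.
#' @export
bin_by_lifespan <- function(results, cfg = analysis_config(),
                            column = "required_total_epo_u_per_l") {
  stopifnot(is.data.frame(results), nrow(results) >= 1,
            column %in% names(results))
  res <- results[results$converged, , drop = FALSE]
  if (nrow(res) == 0) {
    return(data.frame(bin_lo_days = numeric(), bin_hi_days = numeric(),
                      n = integer(), median = numeric(), q1 = numeric(),
                      q3 = numeric(), whisker_lo = numeric(),
                      whisker_hi = numeric(), n_outliers = integer()))
  }
  w <- cfg$lifespan_bin_width
  lo <- lifespan_bin_lo(res$rbc_life_span_days, w)
  out <- lapply(sort(unique(lo)), function(b) {
    s <- boxplot_stats(res[[column]][lo == b])
    data.frame(bin_lo_days = b, bin_hi_days = b + w, n = s$n,
               median = s$median, q1 = s$q1, q3 = s$q3,
               whisker_lo = s$whisker_lo, whisker_hi = s$whisker_hi,
               n_outliers = s$n_outliers)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean required Epo increase on a life-span by Epo-level grid
#'
#' Two-dimensional binning of converged patients: life-span bins as in
#' [bin_by_lifespan()] crossed with endogenous-Epo bins (default edges 5,
#' 15, 25, ... U/L). Each populated cell reports the mean increase of
#' required over endogenous Epo (clamped at zero if the configuration says
#' so) and whether the cell meets the minimum patient count for inclusion.
#' Patients whose endogenous Epo falls below the first bin edge are not
#' assigned to any cell.
#'
#' @param results Output of [solve_population()].
#' @param cfg [analysis_config()].
#' @return A `data.frame` with columns `ls_bin_lo`, `ls_bin_hi`,
#'   `epo_bin_lo`, `epo_bin_hi`, `n`, `mean_delta`, `included`; one row per
#'   populated cell.
#' @export
lifespan_epo_grid <- function(results, cfg = analysis_config()) {
  stopifnot(is.data.frame(results))
  empty <- data.frame(ls_bin_lo = numeric(), ls_bin_hi = numeric(),
                      epo_bin_lo = numeric(), epo_bin_hi = numeric(),
                      n = integer(), mean_delta = numeric(),
                      included = logical())
  if (nrow(results) == 0) return(empty)
  res <- results[results$converged &
                   results$endogenous_epo_u_per_l >= cfg$epo_bin_start, ,
                 drop = FALSE]
  if (nrow(res) == 0) return(empty)
  w <- cfg$lifespan_bin_width
  ew <- cfg$epo_bin_width
  delta_col <- if (cfg$clamp_negative_delta) "delta_clamped_u_per_l"
               else "delta_raw_u_per_l"
  ls_lo <- lifespan_bin_lo(res$rbc_life_span_days, w)
  epo_lo <- cfg$epo_bin_start +
    floor((res$endogenous_epo_u_per_l - cfg$epo_bin_start) / ew) * ew
  key <- paste(ls_lo, epo_lo)
  cells <- !duplicated(key)
  ord <- order(ls_lo[cells], epo_lo[cells])
  out <- do.call(rbind, lapply(which(cells)[ord], function(i) {
    sel <- key == key[i]
    data.frame(ls_bin_lo = ls_lo[i], ls_bin_hi = ls_lo[i] + w,
               epo_bin_lo = epo_lo[i], epo_bin_hi = epo_lo[i] + ew,
               n = sum(sel),
               mean_delta = mean(res[[delta_col]][sel]),
               included = sum(sel) >= cfg$min_cell_count)
  }))
  rownames(out) <- NULL
  out
}
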