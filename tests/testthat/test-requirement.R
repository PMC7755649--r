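test_that("solver hits the hemoglobin window and handles edge cases", {
  model <- calibrated_model()
  cfg <- analysis_config()
  pat <- patient_params(rbc_life_span = 76, endogenous_epo = 15)
  r <- required_total_epo(pat, model, cfg)
  expect_true(r$converged)
  expect_gte(r$achieved_hb, cfg$hb_lo)
  expect_lte(r$achieved_hb, cfg$hb_hi)
  expect_equal(r$delta_clamped, max(0, r$delta_raw))

  # a patient whose endogenous Epo already meets the target needs no
  # increase: solve, then hand the solver a patient with that endogenous
  already <- patient_params(rbc_life_span = 76,
                            endogenous_epo = r$required_total_epo)
  r2 <- required_total_epo(already, model, cfg)
  expect_equal(r2$required_total_epo, already$endogenous_epo_u_per_l,
               tolerance = 1e-6)
  expect_equal(r2$delta_clamped, 0, tolerance = 1e-4)

  # non-achiever: a cap too low to reach the window
  m_cap <- calibrated_model(epo_cap = 1e-3)
  r3 <- required_total_epo(patient_params(rbc_life_span = 40), m_cap, cfg)
  expect_false(r3$converged)
  expect_equal(r3$required_total_epo, 1e-3)

  # over-target at zero Epo: unreachable from above
  m_hot <- calibrate_kappa(model_params(), reference_life_span = 120,
                           reference_epo = 15, reference_hb = 40)
  r4 <- required_total_epo(patient_params(rbc_life_span = 120), m_hot, cfg)
  expect_false(r4$converged)
  expect_equal(r4$required_total_epo, 0)

  expect_error(required_total_epo(pat, model_params(), cfg),
               "uncalibrated")
})

test_that("shorter life span needs more Epo, matching a grid-search oracle", {
  model <- calibrated_model()
  cfg <- analysis_config()
  grid <- seq(0, model$epo_cap, length.out = 2000)
  step <- grid[2] - grid[1]
  grid_oracle <- function(pat) {
    hb <- hb_on_grid(grid, pat, model)
    grid[which.min(abs(hb - (cfg$hb_lo + cfg$hb_hi) / 2))]
  }

  p50 <- patient_params(rbc_life_span = 50)
  p100 <- patient_params(rbc_life_span = 100)
  r50 <- required_total_epo(p50, model, cfg)
  r100 <- required_total_epo(p100, model, cfg)
  expect_gt(r50$required_total_epo, r100$required_total_epo)
  expect_lt(abs(r50$required_total_epo - grid_oracle(p50)), step)
  expect_lt(abs(r100$required_total_epo - grid_oracle(p100)), step)

  # random heterogeneous patients
  pop <- sample_population(10, seed = 99)
  res <- solve_population(pop, model, cfg)
  for (i in seq_len(nrow(pop))) {
    pat <- pop[i, ]
    expect_lt(abs(res$required_total_epo_u_per_l[i] - grid_oracle(pat)),
              step)
  }
})

test_that("boxplot statistics follow the 1.5 IQR fence convention", {
  s <- boxplot_stats(1:5)
  expect_equal(unlist(s[c("median", "q1", "q3", "whisker_lo",
                          "whisker_hi", "n_outliers")]),
               c(median = 3, q1 = 2, q3 = 4, whisker_lo = 1,
                 whisker_hi = 5, n_outliers = 0))
  # hand computation, type-7 quartiles: q1 = 2, q3 = 4, fences [-1, 7]
  s2 <- boxplot_stats(c(1, 2, 3, 4, 100))
  expect_equal(s2$whisker_hi, 4)
  expect_equal(s2$n_outliers, 1)
  # order properties on random input
  set.seed(5)
  for (i in 1:5) {
    v <- rlnorm(50, 3, 1)
    s3 <- boxplot_stats(v)
    expect_true(s3$q1 <= s3$median && s3$median <= s3$q3)
    expect_gte(s3$whisker_lo, min(v))
    expect_lte(s3$whisker_hi, max(v))
  }
  expect_error(boxplot_stats(numeric()), "non-empty")
})

test_that("life-span bins are half-open, aligned, and partition the converged", {
  model <- calibrated_model()
  cfg <- analysis_config()
  res <- data.frame(patient_id = 1:3,
                    rbc_life_span_days = c(35, 44, 47),
                    endogenous_epo_u_per_l = c(10, 12, 14),
                    required_total_epo_u_per_l = c(30, 25, 24),
                    delta_raw_u_per_l = c(20, 13, 10),
                    delta_clamped_u_per_l = c(20, 13, 10),
                    achieved_hb_g_dl = 10.5, converged = TRUE,
                    iterations = 10L)
  b <- bin_by_lifespan(res, cfg)
  expect_equal(b$bin_lo_days, c(30, 40))
  expect_equal(b$n, c(1L, 2L))

  pop <- sample_population(400, seed = 8)
  full <- solve_population(pop, model, cfg)
  bins <- bin_by_lifespan(full, cfg)
  expect_equal(sum(bins$n), sum(full$converged))
  expect_true(all(bins$bin_lo_days %% cfg$lifespan_bin_width == 0))

  # with heterogeneity disabled (only L varies), bin medians decrease
  # with life span
  homo <- pop
  homo$endogenous_epo_u_per_l <- 15
  homo$apoptosis_sensitivity_u_per_l <- 30
  homo$maturation_factor <- 0.5
  hres <- solve_population(homo, model, cfg)
  hbins <- bin_by_lifespan(hres, cfg)
  expect_true(all(diff(hbins$median) < 0))
})

test_that("the life-span by Epo grid applies the minimum cell count", {
  cfg <- analysis_config(min_cell_count = 25)
  mk <- function(n, L, epo, delta) {
    data.frame(patient_id = seq_len(n), rbc_life_span_days = L,
               endogenous_epo_u_per_l = epo,
               required_total_epo_u_per_l = epo + delta,
               delta_raw_u_per_l = delta,
               delta_clamped_u_per_l = pmax(0, delta),
               achieved_hb_g_dl = 10.5, converged = TRUE, iterations = 5L)
  }
  g24 <- lifespan_epo_grid(mk(24, 55, 10, 5), cfg)
  expect_false(g24$included)
  g25 <- lifespan_epo_grid(mk(25, 55, 10, 5), cfg)
  expect_true(g25$included)
  expect_equal(g25$n, 25L)
  expect_equal(g25$mean_delta, 5)
  expect_equal(g25[, c("ls_bin_lo", "ls_bin_hi", "epo_bin_lo",
                       "epo_bin_hi")],
               data.frame(ls_bin_lo = 50, ls_bin_hi = 60, epo_bin_lo = 5,
                          epo_bin_hi = 15))
  expect_equal(nrow(lifespan_epo_grid(mk(5, 55, 10, 5)[0, ], cfg)), 0)

  # homogeneous population: within the 5-15 U/L Epo range, shorter
  # life-span bins require larger mean increases (raw deltas are strictly
  # ordered; clamped ones can tie at zero once endogenous Epo suffices)
  model <- calibrated_model()
  L <- rep(seq(35, 125, by = 10), each = 30)
  homo <- do.call(rbind, lapply(seq_along(L), function(i)
    patient_params(rbc_life_span = L[i], endogenous_epo = 10,
                   patient_id = i)))
  res <- solve_population(homo, model, analysis_config())
  raw_cfg <- analysis_config(min_cell_count = 25,
                             clamp_negative_delta = FALSE)
  g <- lifespan_epo_grid(res, raw_cfg)
  low <- g[g$epo_bin_lo == 5 & g$included, ]
  expect_true(all(diff(low$mean_delta[order(low$ls_bin_lo)]) < 0))
  gc <- lifespan_epo_grid(res, cfg)
  lowc <- gc[gc$epo_bin_lo == 5 & gc$included, ]
  expect_true(all(diff(lowc$mean_delta[order(lowc$ls_bin_lo)]) <= 0))
})
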