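test_that("apoptosis rate has the Hill half-effect and is strictly decreasing", {
  model <- model_params()
  pat <- patient_params(rbc_life_span = 76, apoptosis_sensitivity = 30)
  expect_equal(apoptosis_rate(0, pat, model), model$apoptosis_max)
  expect_equal(apoptosis_rate(30, pat, model), model$apoptosis_max / 2)
  grid <- seq(0, model$epo_cap, length.out = 100)
  a <- apoptosis_rate(grid, pat, model)
  expect_true(all(diff(a) < 0))
  expect_error(apoptosis_rate(-1, pat, model), "non-negative")
})

test_that("production flux saturates at the amplification ceiling and is increasing", {
  pat <- patient_params(rbc_life_span = 76)
  ceiling_flux <- function(model)
    model$stem_influx * exp(model$proliferation_rate *
                              model$proliferation_window)
  # no Epo regulation: flux is the ceiling regardless of E
  m0 <- model_params(apoptosis_max = 0)
  expect_equal(production_flux(c(0, 10, 1000), pat, m0),
               rep(ceiling_flux(m0), 3))
  # Hill limit: apoptosis fully suppressed at very large E
  m <- model_params()
  expect_equal(production_flux(1e9, pat, m), ceiling_flux(m),
               tolerance = 1e-6)
  grid <- seq(0, m$epo_cap, length.out = 200)
  expect_true(all(diff(production_flux(grid, pat, m)) > 0))
})

test_that("analytic steady state is linear in life span and needs calibration", {
  model <- calibrated_model()
  pat50 <- patient_params(rbc_life_span = 50)
  pat100 <- patient_params(rbc_life_span = 100)
  s50 <- steady_state(20, pat50, model)
  s100 <- steady_state(20, pat100, model)
  expect_equal(s100$hemoglobin, 2 * s50$hemoglobin)
  expect_equal(s50$hematocrit, model$hct_per_hb * s50$hemoglobin)
  expect_equal(steady_state(20, patient_params(rbc_life_span = 0),
                            model)$hemoglobin, 0)
  expect_error(steady_state(20, pat50, model_params()), "uncalibrated")
  expect_error(steady_state(model$epo_cap + 1, pat50, model), "cap")
})

test_that("kappa calibration anchors the reference patient and is scale invariant", {
  model <- calibrated_model()
  ref <- patient_params(rbc_life_span = 120, endogenous_epo = 15)
  expect_equal(steady_state(15, ref, model)$hemoglobin, 14.0)
  # direct formula
  expect_equal(model$hb_per_flux,
               14.0 / (production_flux(15, ref, model) * 120))
  # doubling the stem influx and recalibrating changes no hemoglobin
  m2 <- calibrate_kappa(model_params(stem_influx = 2))
  pat <- patient_params(rbc_life_span = 67, apoptosis_sensitivity = 22)
  for (e in c(0, 5, 18, 120))
    expect_equal(steady_state(e, pat, m2)$hemoglobin,
                 steady_state(e, pat, model)$hemoglobin)
  expect_error(calibrate_kappa(model_params(), reference_life_span = -1))
})

test_that("ESA concentration is a superposition of half-life decays", {
  s <- esa_schedule(times = c(2, 5), increments = c(100, 40),
                    half_life = 24)
  expect_equal(esa_concentration(s, 1), 0)       # before first dose
  s1 <- esa_schedule(times = 2, increments = 100, half_life = 24)
  expect_equal(esa_concentration(s1, 3), 50)     # one half-life later
  # superposition: term-by-term evaluation
  tt <- c(2, 4.7, 6, 30)
  term <- function(t0, d, t) ifelse(t >= t0, d * 2^(-(t - t0)), 0)
  expect_equal(esa_concentration(s, tt),
               term(2, 100, tt) + term(5, 40, tt))
  expect_error(esa_schedule(times = c(5, 2), increments = c(1, 1)),
               "non-decreasing")
})

test_that("dynamic simulator converges to the analytic steady state", {
  model <- calibrated_model()
  pat <- patient_params(rbc_life_span = 60, endogenous_epo = 12,
                        apoptosis_sensitivity = 25)
  target <- steady_state(12, pat, model)$hemoglobin
  tr <- simulate_rbc(pat, model, function(t) 12, t_end = 5 * 60, dt = 0.25)
  expect_lt(abs(tail(tr$hemoglobin_g_dl, 1) - target), 1e-3)
  expect_lt(attr(tr, "conservation_error"), 1e-9)
  expect_true(all(tr$hemoglobin_g_dl >= 0))
  expect_error(simulate_rbc(pat, model, function(t) 12, t_end = 10,
                            dt = 0), "positive")
})

test_that("a step Epo increase reaches hemoglobin only after the maturation delay", {
  model <- calibrated_model()
  pat <- patient_params(rbc_life_span = 50, apoptosis_sensitivity = 30,
                        maturation_factor = 0.5)
  t0 <- 300
  dt <- 0.25
  e1 <- 10; e2 <- 40
  epo_fun <- function(t) if (t < t0) e1 else e2
  tr <- simulate_rbc(pat, model, epo_fun, t_end = t0 + 60, dt = dt)
  base <- steady_state(e1, pat, model)$hemoglobin
  after <- tr[tr$time_days > t0, ]
  # monotone approach to the higher steady state
  expect_true(all(diff(after$hemoglobin_g_dl) >= -1e-12))
  # no response before the (post-step) maturation delay has elapsed
  tau_d <- model$maturation_delay / (1 + pat$maturation_factor *
                                       e2 / (e2 + 30))
  first_move <- min(after$time_days[abs(after$hemoglobin_g_dl - base)
                                    > 1e-9])
  expect_gte(first_move, t0 + tau_d - 2 * dt)
})

test_that("neocytolysis at low Epo lowers the steady hemoglobin", {
  model <- calibrated_model()
  m_neo <- calibrated_model(neocytolysis = list(enabled = TRUE))
  pat <- patient_params(rbc_life_span = 76)
  e_low <- 8  # below the neocytolysis Epo threshold
  off <- simulate_rbc(pat, model, function(t) e_low, t_end = 380,
                      dt = 0.25)
  on <- simulate_rbc(pat, m_neo, function(t) e_low, t_end = 380,
                     dt = 0.25)
  expect_lt(tail(on$hemoglobin_g_dl, 1), tail(off$hemoglobin_g_dl, 1))
  expect_lt(attr(on, "conservation_error"), 1e-9)
})
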