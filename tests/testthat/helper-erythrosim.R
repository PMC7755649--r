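# Shared fixtures: a calibrated default model and small random populations.

calibrated_model <- function(...) {
  calibrate_kappa(model_params(...))
}

# Truncated-normal moments, re-exported for oracle checks.
tnorm_moments <- erythrosim:::tnorm_moments

# Steady-state hemoglobin vectorized over an Epo grid (used by the
# grid-search oracle).
hb_on_grid <- function(epo_grid, patient, model) {
  erythrosim:::steady_hb(epo_grid, patient, model)
}
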