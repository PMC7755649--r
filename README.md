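# erythrosim

Biomathematical analysis of how red-blood-cell (RBC) life span drives
erythropoietin (Epo) requirements in hemodialysis patients.

Renal anemia is usually framed as Epo deficiency, but RBCs in hemodialysis
patients also die young — population estimates put their life span around
76 ± 21 days instead of the healthy ~120. A patient whose cells live half
as long must produce (or be dosed toward) roughly twice the replacement
flux to hold the same hemoglobin. `erythrosim` makes that argument
quantitative with a virtual-patient approach, for modelers and
clinician-scientists studying erythropoiesis-stimulating agent (ESA)
hypo-responsiveness:

* **Virtual population generator** — patient parameter sets ("anemia
  avatars") whose RBC life spans follow a truncated normal calibrated to a
  post-truncation mean ± SD of 76 ± 21 days on [33, 137] days, and whose
  endogenous Epo is lognormal with median 15 U/L (quartiles 10.2 and
  21.1 U/L), matching a reported 6,659-patient hemodialysis cohort.
* **Mechanistic erythropoiesis model** — Epo suppresses apoptosis of
  CFU-E progenitors via a Hill function, so the flux into circulation is
  `P(E) = S0 · exp(β·τp − α(E)·τCFU)` with
  `α(E) = αmax·θʰ/(θʰ + Eʰ)`; circulating cells are removed at the
  patient-specific life span `L`, giving the closed-form steady state
  `Hb(E) = κ·P(E)·L`. A dynamic age-structured simulator (maturation
  delay, ESA pharmacokinetics by superposed one-compartment decays,
  optional neocytolysis) reproduces that steady state and handles
  transients.
* **Required-Epo solver** — for each patient, the constant total Epo
  concentration `E*` with steady-state hemoglobin in the target window
  10.49–10.51 g/dl, found by bracketing plus Brent root finding.
* **Population summaries** — box-plot statistics (1.5 IQR fences) of
  required Epo per 10-day life-span bin, and the mean required increase
  over endogenous Epo on a life-span × Epo-level grid including only cells
  with at least 25 patients.
* **Phenomenological hematocrit model** — a single-variable
  production-survival convolution showing that equal ESA dosing yields
  lower hematocrit at shorter life spans.

See the vignette `vignettes/epo-requirement-modeling.Rmd` for the model
assumptions, parameter meanings and design rationale.

## Worked example

```r
library(erythrosim)

pop   <- sample_population(1000, seed = 1)     # virtual patients
model <- calibrate_kappa(model_params())       # anchor: Hb 14 at L = 120 d, E = 15 U/L
res   <- solve_population(pop, model, analysis_config())

r <- required_total_epo(patient_params(rbc_life_span = 50, endogenous_epo = 12), model)
sprintf("E* = %.1f U/L, achieved Hb = %.3f g/dl, increase = %.1f U/L",
        r$required_total_epo, r$achieved_hb, r$delta_raw)
#> "E* = 28.8 U/L, achieved Hb = 10.500 g/dl, increase = 16.8 U/L"

head(bin_by_lifespan(res), 4)
#>   bin_lo_days bin_hi_days   n median   q1   q3 whisker_lo whisker_hi n_outliers
#> 1          30          40  36   42.1 32.1 49.3      14.35       73.6          3
#> 2          40          50  90   28.8 24.1 40.3      15.99       63.2          3
#> 3          50          60 130   26.3 20.3 33.4       9.17       50.9          3
#> 4          60          70 158   22.7 16.6 28.9       6.67       45.8          3

cor(res$rbc_life_span_days, res$required_total_epo_u_per_l, method = "spearman")
#> -0.67
```

A patient with a 50-day RBC life span needs about 29 U/L of total Epo to
hold hemoglobin at 10.50 g/dl — some 17 U/L above their endogenous level —
and the bin medians fall steadily as life span grows, with wide spread
within each bin from heterogeneity in the other patient parameters
(apoptosis sensitivity, maturation response).

The full pipeline (generate → calibrate → solve → bin → grid, all outputs
as CSV plus the echoed effective config) runs from R via
`run_pipeline(load_run_config("config.yaml"))` or from a shell:

```sh
Rscript inst/cli/erythrosim.R all --config config.yaml --seed 1 --out out/
```

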