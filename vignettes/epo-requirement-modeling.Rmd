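---
title: "Modeling how RBC life span drives erythropoietin requirements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling how RBC life span drives erythropoietin requirements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erythrosim)
```

## The question

Hemodialysis (HD) patients with renal anemia are treated with
erythropoiesis-stimulating agents (ESAs) to hold hemoglobin in a narrow
target window. Their red blood cells (RBCs), however, live far shorter than
the healthy ~120 days — cohort estimates center around 76 ± 21 days — so a
substantial part of the ESA dose goes into replacing cells that die early.
`erythrosim` quantifies that relationship *in silico*: it builds a
population of "virtual patients" (parameter sets of an erythropoiesis
model), solves for the constant total serum Epo concentration each patient
needs to sit at a hemoglobin target, and summarizes how that requirement
varies with RBC life span and endogenous Epo level.

## The mechanistic model

The model reduces erythropoiesis to the stages that matter for the
steady-state question:

* Committed progenitors arrive from the stem-cell compartment at a constant
  flux $S_0$ (arbitrary scale) and amplify exponentially at rate $\beta$
  over a proliferation window $\tau_p$.
* During the CFU-E stage (residence $\tau_{CFU}$), cells undergo apoptosis
  at a rate suppressed by Epo through a Hill function,
  $\alpha(E) = \alpha_{\max}\,\theta^h / (\theta^h + E^h)$, where $\theta$
  is the patient's half-effect Epo concentration. Epo is thus a survival
  signal: the flux of cells reaching circulation is
  $$P(E) = S_0\, e^{\beta\tau_p - \alpha(E)\tau_{CFU}},$$
  strictly increasing in $E$.
* New cells enter circulation after a maturation delay
  $\tau_d(E) = \tau_{d0} / (1 + m\,E/(E+\theta))$ — higher Epo releases
  cells earlier (reticulocyte shift), with patient-specific strength $m$.
  The delay affects only transients, not the steady state.
* Circulating RBCs are removed abruptly at the patient-specific life span
  $L$ (rectangular survival). At constant Epo the steady count is then
  exactly $P(E)\,L$ and hemoglobin is $\mathrm{Hb}(E) = \kappa\,P(E)\,L$,
  which serves as a closed-form oracle for the dynamic simulator.
  Hematocrit is reported as $3 \times \mathrm{Hb}$, the usual
  rule-of-three approximation.
* Optionally, *neocytolysis* — selective clearance of young RBCs when Epo
  is low — removes cohorts younger than an age cutoff at an extra rate
  whenever total Epo falls below a threshold. It is off in the headline
  analysis, which holds Epo at or above the patient's need.

Defaults: $\beta = 0.7$/d over $\tau_p = 5$ d, $\alpha_{\max} = 0.35$/d
over $\tau_{CFU} = 6$ d, $h = 2$, $\tau_{d0} = 3$ d, Epo cap
$10^4$ U/L. These produce roughly a 5-fold span between fully suppressed
and maximal apoptosis — enough dynamic range that life span, not the
response ceiling, limits target attainment across the cohort. The absolute
cell scale is not identifiable and never matters: only the product
$\kappa S_0$ enters hemoglobin, and `calibrate_kappa()` fixes it by
anchoring a healthy-physiology reference (life span 120 d at the cohort
median Epo of 15 U/L) to 14.0 g/dl. Rescaling $S_0$ and recalibrating
leaves every output unchanged, and the test suite asserts this invariance.

The neocytolysis sub-parameters are deliberately conservative defaults
(cells younger than 14 days, extra rate 0.05/d below 10 U/L): young-cell
clearance is reported physiology, but its quantitative parameters are not
established, so the term is exposed for dynamic experiments rather than
asserted in the analysis.

## The virtual population

Only two parameter distributions of the reference HD cohort (6,659
patients) are quantitatively reported, and the generator reproduces both:

* **RBC life span** — truncated normal on [33, 137] days whose
  *post-truncation* mean and SD equal 76 and 21 days.
  `fit_truncated_normal()` solves a 2-D problem for the parent
  location/scale, because naively truncating N(76, 21²) to the asymmetric
  range shifts the mean to about 76.9 d. Sampling is by inverse CDF
  restricted to the range, so out-of-range values cannot occur.
* **Endogenous Epo** — lognormal with median 15 U/L. The printed quartiles
  (10.2, 21.1 U/L) are not exactly lognormal-consistent, so
  `fit_lognormal_from_quantiles()` takes the log-median exactly and fits
  the log-SD by least squares over the two quartile equations, giving
  $\sigma \approx 0.539$.

The remaining patient parameters (ESA half-life, apoptosis half-effect
$\theta$, maturation factor $m$) are unreported at the population level.
They default to independent lognormals around plausible central values
(medians 20 h, 30 U/L, 0.5; log-SDs 0.3, 0.4, 0.4). Their role is to
supply realistic between-patient heterogeneity: the spread of $\theta$ in
particular produces the wide within-bin spread of required Epo that
coexists with the clear life-span trend. All of them are configurable, and
correlations between parameters are assumed absent (nothing is reported
about them).

Reproducibility: each parameter draws from its own RNG substream derived
from the root seed, so identical `(n, specs, seed)` give bit-identical
populations and adding a parameter never perturbs the draws of another.

What the generator does *not* emulate: the reference cohort's parameters
were estimated patient-by-patient from real hemoglobin/ESA records, so the
real joint distribution (and any life-span–Epo correlation) is unknown and
not reproduced. Passing tests therefore validate the pipeline's
self-consistency and its qualitative population trends, not the exact
figures obtainable only from the fitted cohort.

## The required-Epo solver

`required_total_epo()` finds the constant total Epo $E^*$ with
$\mathrm{Hb}(E^*)$ at the midpoint of the target window
[10.49, 10.51] g/dl, by doubling an upper bracket from [0, 1] U/L and then
Brent root finding; convergence is declared when the achieved hemoglobin
lies inside the window. "Total Epo held constant to steady state" is the
interpretation used throughout — it matches the requirement being
expressed in concentration units (U/L) and makes the analysis independent
of any dosing schedule or ESA unit conversion. Monotonicity of
$\mathrm{Hb}$ in $E$ guarantees a unique root; a 2,000-point grid search
over $[0, E_{cap}]$ serves as an independent oracle in the tests.

Edge cases: a patient who cannot reach the window below the Epo cap is
returned `converged = FALSE` with the cap as the requirement; a patient
already above the window at zero Epo (possible only for extreme
calibrations) is non-converged with requirement 0. Neither occurs on the
default population. Negative increases (endogenous Epo exceeding the
requirement, common at long life spans) are clamped to zero for the grid
summaries but kept raw in the per-patient table.

Summaries mirror the field's presentation: box statistics (type-7
quartiles, 1.5 IQR fences, whiskers at the most extreme non-outliers) of
required Epo per 10-day life-span bin aligned to multiples of 10; and mean
required increase on the life-span × endogenous-Epo grid with bin edges 5,
15, 25, … U/L, reporting only cells holding at least 25 patients. Because
it is ambiguous whether a per-bin summary should show total required Epo or
the increase over endogenous, `bin_by_lifespan()` can summarize either
column. Patients below the first Epo edge (about 2% of the cohort) fall
outside the grid.

## The phenomenological model

For the qualitative dose–hematocrit claim, a single-variable model is
included: hematocrit is the convolution of an effective production rate
with a survival kernel,
$$H(t) = \int_0^t p(C(s))\,S(t-s)\,ds,$$
with $p(C) = p_0 + \eta \max(0, C - \theta_c)$ (linear above the response
threshold — the simplest form consistent with "efficacy plus threshold";
saturation is left to configuration extensions) and a logistic kernel
$S(a) = 1/(1+e^{(a-L)/s_L})$ encoding life span and its variability with a
single spread parameter. At $s_L = 0$ the kernel is rectangular, taken as
the pointwise logistic limit (value ½ at $a = L$) so trapezoid quadrature
of the convolution reproduces the closed form $H = p_0 L$ exactly on
grid-aligned life spans. The model reproduces two qualitative properties:
equal constant dosing yields lower steady hematocrit at shorter $L$, and
the excursion after a single dose persists longer at longer $L$.

## Numerical choices

* Age-structured simulation: uniform age grid with spacing `dt`
  (default 0.25 d); the cohort straddling age $L$ is removed pro rata, so
  the steady count equals $P\,L$ exactly rather than to $O(dt)$. Cohort
  conservation (entering − removed = change) holds to ~1e−16 relative per
  step and is asserted at 1e−9.
* The truncated-normal calibration targets 1e−6 relative moment error
  (BFGS with a Nelder–Mead fallback on location/log-scale).
* Brent tolerance is scaled to the bracket; achieved hemoglobins land
  ~1e−9 g/dl from the window midpoint.
* Ties and degenerate inputs: zero life span gives zero hemoglobin; empty
  bins produce no summary rows; an empty grid input returns an empty grid.

Problem sizes: the full analysis (6,659 patients) runs in a few seconds
via the analytic steady state. The test suite exercises the dynamic
simulator on horizons of 5 L days at `dt = 0.25`, Monte-Carlo oracles at
n = 10⁶ draws, and population properties at n = 400–6,659 — sizes chosen
so each check is statistically meaningful while the suite stays
interactive.

## Known limitations

* Iron availability, inflammation and other hypo-responsiveness factors
  are not modeled; their effects are only implicitly present in the
  effective parameters.
* The mechanistic stage structure is deliberately minimal (one
  Epo-sensitive stage, fixed stage durations); it is faithful to the
  qualitative regulation — Epo suppresses CFU-E apoptosis — but not a
  full age–maturity PDE of the bone-marrow hierarchy.
* The fixed hematocrit/hemoglobin ratio ignores per-cell hemoglobin
  variation.
* Required Epo is a constant concentration, not an ESA dosing schedule;
  converting between the two would need the pharmacokinetic layer
  (`esa_schedule()`/`simulate_rbc()`) plus a unit model for the specific
  agent.
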