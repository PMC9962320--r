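---
title: "External evaluation of methotrexate PopPK models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{External evaluation of methotrexate PopPK models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtxppk)
```

## The problem

High-dose methotrexate (HD-MTX) in pediatric acute lymphoblastic leukemia
is dosed at 1–5 g/m² per course, infused over 24 h (10% over the first
0.5 h, 90% over the remaining 23.5 h), and monitored by plasma samples
drawn roughly every 24 h until the concentration falls below 0.1 µmol/L.
Several population-pharmacokinetic (PopPK) models of this regimen have
been published, each reporting typical clearances and volumes, covariate
relations (body size, renal function, age, sex), log-normal
inter-individual variability (IIV), and residual error. Whether any of
them predicts well enough for model-informed precision dosing in a *new*
population is an empirical question — external evaluation. `mtxppk`
implements that evaluation as a reusable, tested pipeline, and — because
the underlying clinical dataset of such studies is rarely shareable —
ships a synthetic-cohort generator that emulates the validation cohort's
design, so every claim the package makes is backed by code that runs.

## The model catalog

Six published models are transcribed declaratively
(`build_model_catalog()`): five two-compartment models and one
three-compartment model (Gao). Parameters are typical values multiplied
by covariate functions, e.g. allometric weight scaling
`CL = 6.9 × (weight/19)^0.75` with a linear creatinine effect (Gao), BSA
power functions (Hui, Medellin-Garibay, Zhang), an age-branched
micro-constant model (Aumente, with fixed K₁₂ = 0.0155 h⁻¹ and
K₂₁ = 0.0724 h⁻¹), and pure weight proportionality (Jonsson). Each
covariate relation is stored as an R expression over a fixed vocabulary
(`weight`, `bsa`, `egfr`, `scr_umol`, `age`, `sex_female`, `oh`), so the
catalog round-trips through YAML and can be extended without code
changes.

Random effects are log-normal: each parameter with listed IIV is
`typical × e^η`, and the Hui clearance additionally carries a per-course
(inter-occasion) `e^κ`. Published variabilities are CV percentages; by
default we read CV/100 directly as the standard deviation ω of η. The
exact log-normal convention ω² = ln(1 + CV²) is available
(`omega_matrix(..., convention = "lognormal")`), but with published CVs
up to 137.6% the approximate convention is the only self-consistent
reading of the source values, so it is the default.

Decisions made where the sources were ambiguous, all configurable in
`build_model_catalog()`:

* **Gao creatinine units.** The relation `1 + (Scr − 26) × (−0.0097)`
  only makes physiological sense with creatinine in µmol/L (reference 26
  ≈ 0.29 mg/dL); covariate records carry both units and convert at
  1 mg/dL = 88.42 µmol/L.
* **Gao random effects.** The structural equations mark η on CL and V₂
  while the variability table labels the second value V₁; we follow the
  structural equations (CL 17.9%, V₂ 26.2%).
* **Hui renal term.** `(eGFR × 1.73/192 × BSA)^0.256` is parenthesized
  ambiguously; the default reading normalizes the *absolute* GFR,
  `((eGFR × BSA/1.73)/192)^0.256` — eGFR is indexed to 1.73 m², so
  multiplying by BSA/1.73 de-indexes it and 192 mL/min is the reference.
  The literal left-to-right reading is kept behind
  `hui_renal = "literal"`.
* **Zhang sex coding.** Gender = 1 for girls (default), so the negative
  coefficient lowers female clearance; configurable because the source
  does not state the coding.
* **Zhang alkalinization volume (OH).** The validation-style dataset has
  no OH; the original study's central value is not reproduced here, so
  there is no built-in default — supply one via
  `zhang_oh_default` or provide the covariate. The simulator generates OH
  directly.
* **Aumente age branch.** Age exactly 10 years uses the older-age
  equations.
* **Jonsson residual error** is not reported; a 30% proportional error is
  assumed, the convention for evaluating such models.
* **BSA formula** (recorded but never specified in the sources):
  Mosteller `sqrt(height × weight/3600)` by default, DuBois available.

```{r catalog}
catalog <- build_model_catalog()
cov <- covariate_record("ref", "M", age_yr = 5.5, weight_kg = 19,
                        height_cm = 113, scr_umol = 26)
typical_params(catalog$gao, cov)$values
```

## The PK engine

All six models are linear mammillary systems `dA/dt = M A + input` with
amounts in µmol (methotrexate molar mass 454.44 g/mol), so central
concentration is `A₁/V₁` in µmol/L. Infusions are piecewise-constant
inputs; within each segment the solution is exact:
`A(t+h) = A_ss + e^{Mh}(A(t) − A_ss)` with `A_ss = −M⁻¹ r`. The matrix
exponential is computed through a symmetrized eigendecomposition — with
`s_j = sqrt(k_{1j}/k_{j1})` the similarity `diag(1/s) M diag(s)` is
symmetric, so eigenvalues are real and the decomposition is stable and
cheap enough for the estimation hot loop (one decomposition per occasion
per objective evaluation). Segments are delimited by every infusion edge,
occasion boundary and query time; a query time on a boundary is evaluated
as the end of the completed segment (concentrations are continuous, so
this matters only for the bookkeeping of input rates).

This propagator was chosen over closed-form biexponential macro-constants
because it covers the three-compartment Gao model, occasion-varying
parameters and overlapping courses uniformly. `ode_reference()` solves
the same system with `deSolve::lsoda` at tight tolerances and serves as
an independent oracle: the test suite holds the two routes to within
1e-6 relative error over randomized 2- and 3-compartment draws, and also
checks dose linearity, time-shift equivariance, superposition, mass
balance and the bolus biexponential limit.

## MAP-Bayesian forecasting

Population predictions (PRED) set all random effects to zero. Individual
predictions (IPRED) condition on the patient's quantified concentrations
through the posterior mode (empirical Bayes, NONMEM's posthoc step with
`MAXEVAL=0`): minimize

$$\sum_i \left[\ln 2\pi\sigma_i^2 + \frac{(y_i - f_i(\eta,\kappa))^2}{\sigma_i^2}\right]
  + \eta^\top\Omega^{-1}\eta + \sum_{occ}\kappa^\top\Omega_{IOV}^{-1}\kappa,$$

with `σ_i² = (prop × f_i)² + add²` evaluated at the individual
prediction — the standard posthoc variance. Numerical choices:

* **Optimizer**: L-BFGS-B from η = 0 plus four jittered starts
  (SD 0.5) — published ωs up to 137.6% CV can create local minima. The
  jitter stream is derived from the optimizer-config seed only, so
  identical patients always get identical estimates. Bounds ±8 on each
  η/κ; degenerate points (non-finite predictions, underflowed variance)
  return a large finite penalty, which box-constrained quasi-Newton
  handles where `Inf` would abort.
* **Convergence**: projected-gradient tolerance 1e-8; if the line search
  aborts first (common on near-noise-free objectives), the point is
  accepted as converged when its central-difference gradient max-norm is
  below 1e-3. The best of all starts is returned, and never a point worse
  than the prior mode.
* **BLQ handling**: observations below the 0.05 µmol/L LLOQ are flagged
  at read time and excluded from fitting and from all metrics; no
  censored-likelihood (M3) term is used, matching an evaluation that
  reports quantified samples only.
* **Occasions**: each HD-MTX course opens an occasion; κ is estimated
  only for occasions carrying observations, others stay 0. With IOV only
  the per-occasion sum η + κ is identified by the data — the prior
  allocates the split — so recovery tests for the Hui model assert the
  sum, not the components.
* **Interaction caveat**: because σ² depends on η through f, the
  objective's optimum is not exactly η = 0 even when an observation
  equals the typical prediction, and the "infinite residual variance ⇒
  η̂ → 0" shrinkage limit is exact only for additive error. The tests
  encode both facts.

## Evaluation statistics

For each retained observation, `PE_i = (C_{i,pred} − C_{obs})/C_{obs} ×
100`; summaries are the median PE, the mean (MPE) and the root mean
square (RMSE), computed separately for PRED and IPRED. A model is
acceptably unbiased when |median PE| and |MPE| are both strictly below
20%, and acceptably precise when RMSE ≤ 30% (inclusive). RMSE ≥ |MPE|
(Jensen) is asserted on every summary. Bland-Altman limits are
mean ± 1.96 × SD of the PE; the reference axis defaults to the
observation/prediction mean (the source figures specify only the
y-construction, so the conventional x is used, switchable to the
observation). Patients whose MAP fit fails are excluded from IPRED
summaries, retained in PRED, and counted in the report — never silently
dropped.

## The synthetic cohort

The generator (`cohort_config()`, `simulate_cohort()`) emulates the
validation cohort's *design*: n = 51, age 1–13 y (median 5.5), weight
9.5–62 kg (median 19), height 73–168 cm, creatinine 0.16–0.71 mg/dL
(median 0.31), 40/51 boys; risk-dependent doses (3 g/m² low-risk, 5 g/m²
otherwise); two courses 336 h apart; nominal samples at 24/48/72/96 h
after each course start with N(0, 1 h) jitter truncated at ±3 h
("actual sampling times may deviate slightly"); sampling stops after the
first value below 0.1 µmol/L; values below 0.05 µmol/L are flagged BLQ.
Under these defaults a 51-patient cohort yields on the order of 300
observations (the validation dataset had 354 from two-or-more courses per
child; per-patient course counts are not published, so two is the
default).

Design notes:

* Age is a truncated log-normal centred on the median age (sdlog 0.5).
  A log-uniform draw over the range was considered and rejected: its
  median (3.6 y) drags the weight median ~16% below the cohort's 19 kg.
* Height and weight are coupled to age through a packaged growth-anchor
  table (`inst/extdata/growth_anchors_synthetic.csv` — a synthetic
  approximation of pediatric growth medians, tuned so age 5.5 y maps to
  113 cm/19 kg) with multiplicative log-normal noise, so height, weight
  and BSA are jointly plausible rather than independent marginals.
* Unpublished quantities were fixed once at field-plausible values:
  risk mix 50/35/15% (LR/IR/HR), alkalinization volume log-normal
  (median 200 mL, sdlog 0.4, clipped 50–1000 mL), creatinine sdlog 0.25,
  height/weight log-SDs 0.03/0.12.
* All randomness flows through the mandatory seed; per-patient substreams
  are derived from the patient index, so cohorts are reproducible
  records-for-records.

What the simulator does *not* reproduce: real TDM data have recording
errors, delayed-elimination outliers (third-space accumulation), renal
impairment, leucovorin-rescue effects and informative sampling (extra
samples for slow eliminators beyond the simple stop rule). Passing
self-consistency tests on synthetic cohorts therefore demonstrates that
the pipeline is correct, not that any model predicts real external data
well — the published external evaluation found all six models imprecise
(RMSE > 30%) on real patients, and reproducing those exact numbers would
require their non-deposited dataset.

## Problem sizes and runtime choices

The test suite cross-checks the solver on 200 randomized parameter draws,
verifies the MAP optimizer against two-stage brute-force grids (final
step 1e-4 in 1-D, 1e-3 in 2-D, matching the 1e-3 assertion band),
recovers generating η from 18-sample low-RUV patients, and runs the
end-to-end self-consistency experiment at the full 51-patient size over
five seeds (IPRED |MPE| < 10%, IPRED RMSE ≤ PRED RMSE by majority). The
sparse 24/48/72/96 h TDM design cannot identify V₁ from data — recovery
fixtures therefore use a dense design with early (0.5–4 h) and
post-infusion samples; this is an identifiability fact, not an optimizer
limitation (the objective at the estimate is verifiably below the
objective at the truth).

## Known limitations

* No nonlinear elimination, absorption or 7-OH-metabolite kinetics; no
  delayed-elimination phenotypes.
* No censored-data likelihood for BLQ records.
* No population re-estimation (FOCE/SAEM), no uncertainty on η̂, no
  dose-optimization layer.
* The omega convention (CV as SD of η) is an interpretation; both
  conventions are implemented and the choice is explicit everywhere it
  matters.
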