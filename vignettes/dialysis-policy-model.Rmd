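---
title: "The dialysis policy model: structure, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dialysis policy model: structure, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dialysisCEA)
```

## The decision problem

Indonesia's national insurer reimburses dialysis for end-stage renal disease
(ESRD), overwhelmingly as hemodialysis (HD), although peritoneal dialysis
(PD) is cheaper per patient-year and PD-first programmes elsewhere in Asia
have expanded access at lower cost. `dialysisCEA` evaluates three policies
for incident ESRD patients — PD-first, HD-first, and conservative supportive
care — on lifetime costs (2015 IDR), life years (LY) and quality-adjusted
life years (QALYs), from both a societal and a healthcare-provider
perspective, and projects the payer budget of each dialysis policy over five
years.

## Model structure

The core is a Markov cohort state-transition model. Living dialysis patients
occupy PD or HD; each modality has a temporary complication sub-state
(peritonitis for PD, vascular-access complications for HD) entered and left
within a single annual cycle; death is absorbing. Supportive care is a
single living state on a monthly clock. Kidney transplantation is not
modelled (donor scarcity makes it marginal in this setting), and mortality
is not age- or sex-structured.

Dialysis arms use one-year cycles. Within a cycle the cohort experiences,
in order:

1. **death**, with the registry annual probability for that year
   (`effective_death_prob()`); the observed schedule covers years 1–6
   (0.224, 0.135, 0.122, 0.059, 0.063, 0.146) and the year-6 value is
   carried forward as a constant hazard. The same schedule applies to both
   modalities: the registry follow-up is of HD patients, no local PD
   survival exists, and published comparisons find no material difference —
   so the dialysis arms differ only in costs and quality of life, never in
   survival.
2. **modality switching** among survivors, with annual probabilities 0.350
   (PD to HD) and 0.111 (HD to PD). Switching is a recurring annual risk in
   both directions under either policy, not a once-per-lifetime event: the
   model is memoryless, and a policy determines only the starting modality.
3. **complication episodes**: an occupant of PD (HD) experiences peritonitis
   (a vascular-access complication) with annual probability 0.252 (0.041),
   spends `complication_months` (default 1) of that year in the complication
   sub-state at the complication utility and returns to the base state.

Supportive care uses monthly cycles with a constant death probability of
0.405 per month. The source table gives this expert-opinion value without a
time unit; the monthly reading is adopted because it implies a life
expectancy of 1/0.405 months ≈ 0.21 years, consistent with the reported
result, while an annual reading would imply several years of survival
without dialysis, clinically implausible in this population.

## Accrual and discounting conventions

The reference evaluation was built in a spreadsheet and does not state its
cycle conventions, yet the printed LY, QALY, lifetime-cost and ICER values
jointly pin them down rather tightly. The package therefore fixes, as its
own calibrated convention:

* **Costs** accrue at the **start** of each cycle, to everyone alive at
  cycle start, in their start-of-cycle modality, discounted at cycle-start
  time (`1.03^-(t-1)`). A patient who dies during a year is charged that
  year's treatment (costs are committed up front). The year's direct
  medical cost is maintenance plus the complication probability times the
  annual complication-treatment cost; the expected switch-initiation flow
  (alive × switch probability × new modality's initiation cost) is charged
  the same way; the entry initiation cost is charged undiscounted at entry.
* **Life years and QALYs** accrue at the **end** of each cycle, to
  survivors only, in their end-of-cycle modality, discounted at cycle-end
  time (`1.03^-t`). Deaths contribute nothing in their death year. A
  complication episode contributes the complication utility for
  `complication_months/12` of the year.
* **Supportive care**: the month of death is lived (death at month end), so
  expected months lived equal the geometric mean 1/p; the medical cost
  (444,400 IDR) is charged per month and the household (direct non-medical)
  cost of 274,881 IDR once at entry. The per-month reading of the medical
  cost reproduces the reported provider-perspective total (1.1M IDR);
  the reported societal total (1.7M) is not exactly reconcilable with the
  input table under any reading we examined (the package computes 1.37M),
  a discrepancy that moves ICERs by well under one percent.
* **Horizon**: `horizon_years = 24` annual cycles operationalises the
  "lifetime" horizon. Residual survivorship is below 3% at that point, and
  24 is the value at which the model jointly reproduces the reported life
  expectancy, QALYs, lifetime costs and ICERs most closely; the horizon is
  a setting, not a constant.
* Half-cycle correction is deliberately not applied: the start/end split
  above is what matches the reference results.

Under these conventions the model at the mean inputs yields LY 6.00 (both
dialysis arms), QALYs 4.42 / 4.33 (PD-first / HD-first), societal discounted
lifetime costs 686.8M / 731.5M IDR and ICERs versus supportive care of
190.4M / 207.6M IDR per QALY — each within about 1.5% of the reported
values (5.93; 4.40 / 4.34; 696.6M / 735.4M; 193.2M / 207.4M). The residual
disagreement is the footprint of whatever further spreadsheet conventions
the original model used; we document ours and treat them as the package's
definition.

The societal perspective adds annual household direct non-medical costs
(travel, food; 1.55M PD vs 9.00M HD — HD requires thrice-weekly facility
visits) and caregiver income loss (1.74M vs 3.16M) to the provider
perspective's direct medical costs.

## Parameter uncertainty

Every input is a mean / standard-error / family triple. PSA draws use
method-of-moments fits: Beta for probabilities and utilities
(`beta_from_moments()`), Gamma for costs (`gamma_from_moments()`). Two
probability rows (the complication probabilities) carry a Gamma family in
the source table with standard errors so large that a Beta fit would be
infeasible (se² ≥ mean(1−mean)); they are drawn from the fitted Gamma and
truncated to [0, 1], and `validate_parameters()` emits a warning so the
reinterpretation is never silent. Parameters with `se = 0` are fixed, which
lets deterministic runs flow through the PSA code path unchanged. The
supportive-care utility is structurally tied to the HD-with-complication
utility (0.37), the standard assumption when no utility for conservative
care is measured.

`run_psa()` (default 1,000 draws) samples one parameter set per iteration
and evaluates all three policies on that shared draw — common random
numbers, which reduce the Monte-Carlo variance of incremental quantities;
the reference analysis is silent on this and nothing in its outputs
distinguishes the choices. The CEAC assigns each draw to the policy with
the highest net monetary benefit; exact ties are split equally so the
probabilities always sum to one. At a willingness to pay of 43M IDR (one
GDP per capita) supportive care is optimal in essentially every draw; the
PD-first policy first leads the curve at 190M IDR per QALY on the default
2M-step grid, stable across seeds. HD-first, dominated at the means, never
leads.

Reported ICERs come in two flavours: the deterministic ICER at the mean
inputs and the across-draw mean of per-draw ICERs (`psa$mean_icer`); the
reference text suggests it reported PSA means, and the two agree to well
within Monte-Carlo noise here, so both are exposed.

## Budget impact

`run_bia()` projects payer (direct-medical, undiscounted) spending for a
policy and coverage scenario: year 1 enrolls coverage × (prevalence 63,818 +
incidence 17,913), each later year adds coverage × incidence as a new entry
cohort, and every cohort evolves through the same engine (mortality
attrition on by default, switchable off). The reference publication's own
budget totals are internally inconsistent between its summary and results
sections and cannot be reconstructed from the input table under any simple
patient-count construction we tried; the budget module is therefore held to
structural properties — PD-first strictly cheaper than HD-first every year
and cumulatively at both coverages, exact linearity in coverage, and
monotonicity in every unit cost — rather than to the printed trillions.

## Validation against a patient-level oracle

`run_microsim()` implements the identical event model patient by patient
(annual event draws recorded on a monthly timeline; two independent
complication draws per year mirror the cohort engine's use of the
start-of-cycle modality for complication *costs* and the end-of-cycle
modality for complication *disutility*), and `generate_synthetic_survey()`
regenerates questionnaire-like per-patient cost and utility samples whose
moments converge to the input table (standard errors of the means scaled to
patient level via the study's arm size of 52). The test suite requires the
cohort engine's LY, QALYs and both cost perspectives to sit within three
Monte-Carlo standard errors of a 100,000-patient microsimulation for the
default inputs (and 20,000–30,000 patients for random parameter draws), the
trace to conserve occupancy to 1e-9 at every cycle, dead occupancy to be
monotone, PSA results to be bit-identical under a fixed seed, and the
survey round trip to recover the input means.

What the synthetic data do **not** emulate: real questionnaire structure
(demographics, item-level responses), correlation between a patient's costs
and utilities, regional tariff variation, or non-constant hazards within
the supportive arm. Passing tests therefore demonstrate internal
consistency of the implementation and faithfulness to the published inputs,
not external validity of those inputs.

## Numerical choices and degenerate inputs

* Supportive traces stop when residual living occupancy drops below 1e-9
  (about 40 monthly cycles at the default death probability) or at the
  horizon; a death probability of 1 produces a single one-month cycle.
* Occupancy conservation is asserted inside the engine (tolerance 1e-9) and
  violations raise rather than warn.
* Beta moment matching refuses infeasible variances (se² ≥ mean(1−mean));
  infeasibility is a configuration error at setup, not a per-draw event.
* In the frontier, strictly dominated options are removed first, then
  extended dominance enforces non-decreasing sequential ICERs; collinear
  middle points are removed (they add cost without changing the frontier).
* `ceac_crossing()` returns the smallest grid point at which a policy's
  probability strictly exceeds all others', and `NA` if that never happens;
  no interpolation between grid points is applied by default.
* Money is carried in raw IDR end to end and only formatted to millions
  (CEA) or trillions (BIA) for display.

## Limitations

The model inherits the reference study's scope: one survival schedule for
both modalities (no modality-specific mortality), no transplantation state,
no age structure, complication risks and costs constant over time, no
correlation between sampled parameters, and cost data from three hospitals
in one tariff year. The accrual conventions and horizon, while calibrated
and documented, remain a reconstruction; analysts who prefer other
conventions can change the horizon, complication duration and switching
behaviour through `analysis_settings()` and re-run everything, but the
start-of-cycle cost / end-of-cycle outcome split is fixed in code as the
package's definition of the model.
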