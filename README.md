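# dialysisCEA

Economic evaluation of dialysis policy options for end-stage renal disease
(ESRD) under universal health coverage in Indonesia. The package implements a
Markov cohort state-transition model comparing three policies for incident
ESRD patients:

- **PD-first** — peritoneal dialysis as initial treatment, hemodialysis after
  complications or switching;
- **HD-first** — hemodialysis first, peritoneal dialysis after complications
  or switching;
- **supportive care** — conservative management without dialysis.

It is written for health economists and HTA analysts who want to reproduce,
stress-test or extend the dialysis-policy evaluation: every input (survival,
transition probabilities, 2015-IDR costs, EQ-5D-3L utilities, each with mean,
standard error and distribution family) lives in a versioned YAML config, and
every published quantity is recomputed by code.

## The model

Living patients occupy one of the states PD, HD (with temporary
peritonitis / vascular-access complication sub-states) or supportive care;
death is absorbing. Dialysis arms run on one-year cycles: death by the
registry schedule \(q_t\) (years 1–6, constant hazard beyond), then modality
switching among survivors (annual probabilities \(p_{PD\to HD}=0.350\),
\(p_{HD\to PD}=0.111\)), then complication episodes lasting one month of the
year. Supportive care runs on monthly cycles with death probability 0.405
per month. Lifetime (discounted) cost and QALYs accrue per cycle,

\[ C = \sum_t d(t-1)\,n_t\,c(s_t), \qquad
   Q = \sum_t d(t)\,\tilde n_t\,u(\tilde s_t), \qquad d(t) = 1.03^{-t}, \]

with costs charged at cycle start to everyone then alive (\(n_t\)) in their
start-of-cycle state and outcomes credited at cycle end to survivors
(\(\tilde n_t\)); see the methods vignette for why this convention is used.
Policies are compared by incremental cost-effectiveness ratios
\( \mathrm{ICER} = \Delta C / \Delta Q \) with dominance analysis,
probabilistic sensitivity analysis (moment-matched Beta/Gamma sampling,
1,000 draws) summarised as cost-effectiveness acceptability curves
\( \Pr[\text{policy maximises } \lambda Q - C] \) over willingness-to-pay
\(\lambda\), and a five-year payer budget impact projection.

A patient-level microsimulation implements the identical event model and
serves as an independent oracle: cohort expectations must match simulated
averages within Monte-Carlo error. A synthetic survey generator emulates the
questionnaire data behind the cost and utility inputs.

## Worked example

```r
library(dialysisCEA)
params <- default_parameters()          # bundled input table
settings <- analysis_settings(seed = 1) # 3% discounting, 24-year horizon
run_cea(params, settings)
```

```
<cea_result> deterministic cost-effectiveness analysis
     policy ly_undiscounted qaly_undiscounted qaly_discounted
   PD_FIRST            6.00              4.42            3.68
   HD_FIRST            6.00              4.33            3.59
 SUPPORTIVE            0.21              0.08            0.08
 cost_discounted_societal cost_discounted_provider
                   686.8M                   638.7M
                   731.5M                   668.0M
                     1.4M                     1.1M
<cea_frontier> societal perspective
     policy   cost  qaly    status        icer
 SUPPORTIVE   1.4M 0.076  frontier           -
   HD_FIRST 731.5M 3.592 dominated           -
   PD_FIRST 686.8M 3.676  frontier 190.4M/QALY
```

Both dialysis policies yield the same 6.0 undiscounted life years (they share
one survival schedule), but PD-first gains more QALYs (4.42 vs 4.33, PD
patients report higher utility) at a lower societal lifetime cost (686.8M vs
731.5M IDR), so HD-first is dominated. Against supportive care, PD-first
costs 190.4M IDR per QALY gained — far above the one-GDP-per-capita threshold
of 43M IDR, at which supportive care remains the preferred option.

```r
psa <- run_psa(params, settings)   # 1,000 draws
curve <- ceac(psa)
ceac_crossing(curve, "PD_FIRST")   # 1.9e+08: PD-first leads beyond 190M IDR/QALY
run_bia(bia_inputs(coverage = 0.53), params, "PD_FIRST")
```

The budget table reports per-year and cumulative payer cost (provider
perspective, undiscounted) for each coverage scenario; PD-first stays below
HD-first in every year.

A command-line wrapper (`inst/cli/dialysis-cea`) exposes `run-cea`,
`run-psa`, `run-bia` and `validate-config` with CSV/JSON outputs and a
reproducibility manifest.

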