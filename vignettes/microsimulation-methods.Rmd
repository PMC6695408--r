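---
title: "Methods: an annual-cycle microsimulation of glycemic progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an annual-cycle microsimulation of glycemic progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(prediasim)
```

## Model overview

`prediasim` simulates individual adults through three glycemic states —
no diabetes, prediabetes, and diabetes — one year at a time. Diabetes is
absorbing: the model has no remission path out of diagnosed diabetes,
while prediabetes may revert to normoglycemia. Each agent carries age
(years), gender, body-mass index (BMI, kg/m²), glycemic state, vital
status, and the year of diabetes onset when applicable.

Transition probabilities are stratified by:

* **17 five-year age bands**, 20–24 through 100+ (internally indexed
  0–16);
* **gender** (male, female);
* **3 BMI categories**: normal (< 25), overweight ([25, 30)), obese
  (≥ 30). BMI category boundaries are half-open on the left, so a BMI of
  exactly 25 is overweight and 30 is obese.

This yields 102 strata × 3 origin states = 306 transition rows, held in a
`tpm_set` object whose rows always sum to one and whose diabetes rows are
always (0, 0, 1).

## The annual cycle

Each simulated year applies, in this fixed order:

1. **Mortality.** Each alive agent dies with the life-table probability
   for their age and gender; agents who have ever been diabetic instead
   use the diabetic-mortality model (below).
2. **Intervention** (first simulated year only, when one is supplied).
   Eligible agents — alive, prediabetic, aged within the program's band
   (default 25–65 inclusive), BMI ≥ 25 — all participate and incur the
   per-person cost. A fraction of participants (the achievement rate)
   realizes the program's proportional BMI reduction, floored at BMI
   18.5.
3. **Aging and BMI drift.** Alive agents age one year. With probability
   `p_change` (per age-band × gender), BMI moves by a Normal draw whose
   mean is `mean_change / p_change` (so the unconditional mean change is
   `mean_change`) with standard deviation 0.5, floored at BMI 15.
4. **Glycemic transition.** Each alive agent draws its next state from
   the transition row for its current stratum and state.

After the four phases, that year's population entrants (default: young
adults aged 20–24) are appended. Per-year incidence, prevalence, and
mortality are recorded *before* entrants are added, so the published
rates always describe the cohort that was actually simulated through the
year.

Incidence is new cases per 100 alive agents not previously diagnosed;
prevalence is diabetic agents per 100 alive; diabetes mortality is
deaths of ever-diabetic agents per 100 alive at the start of the year.

## Common random numbers

All randomness flows from one master integer seed. Every (year, phase)
pair derives its own substream seed via `substream_seed()`, and each
phase draws a uniform for *every* agent row — including dead ones — so
consuming draws in one phase never desynchronizes another. Dead agents
are retained in place, and entrants are appended identically in both
arms of a paired run. Consequently two runs with the same master seed
are aligned row-for-row: a control arm and an intervention arm differ
only where the intervention actually changed an agent's path. With a
zero-achievement intervention the two arms are bit-identical.

`paired_run()` exploits this to isolate intervention effects agent by
agent at far lower variance than independent runs would allow.

## Diabetic mortality and calibration

For ever-diabetic agents the annual death probability is

$$ p = 1 - \exp\{-h_0 \exp(\eta + c)\}, \qquad
   \eta = \beta_{age}(age - 50) + \beta_{male}\,[male] +
          \beta_{bmi}(BMI - 28), $$

a discrete-time proportional-hazards form with baseline hazard $h_0$
(default 0.02/yr) and log-hazard slopes $\beta_{age} = 0.085$ per year,
$\beta_{male} = 0.35$, $\beta_{bmi} = 0.025$ per kg/m². The shift $c$
(default 0) is a calibration constant: `calibrate_mortality_constant()`
finds, by bisection on $[-10, 10]$, the $c$ at which a reference cohort's
expected annual mortality rate matches a target rate per 100. Because
$p$ is strictly increasing in $c$, the calibrated constant is monotone
in the target; targets outside the achievable bracket raise an error.
The deterministic `"expected"` method averages the closed-form
probabilities; `"simulate"` draws deaths under a fixed seed.

## Estimating transition matrices from panel data

`estimate_tpms()` takes longitudinal panel visits (subject, month, age,
gender, BMI, observed state) and forms transition pairs from consecutive
visits whose spacing is within ±25% (the `slack`) of the nominal
interval. Row probabilities are counting maximum-likelihood estimates.
Two refinements matter in practice:

* **Hierarchical pooling.** Strata with fewer than `min_pairs` observed
  pairs borrow counts from progressively coarser levels — pooling over
  BMI, then over BMI and gender, then over neighboring age bands — and
  the level actually used for each row is recorded in the `"pooling"`
  attribute.
* **Annualization.** Panels observed at non-annual intervals are
  converted to annual matrices by matrix power: a 6-month matrix is
  squared, and fractional powers use the eigendecomposition with rows
  projected back onto the probability simplex. If the eigen route
  produces an invalid matrix, a linear rescaling fallback is used with a
  warning. Diabetes rows are forced absorbing throughout, and
  `smooth_tpms()` offers additive (Dirichlet) smoothing against the
  observed pair counts.

In testing, a homogeneous truth with 5,000 subjects and 4 annual visits
is recovered with maximum absolute error below 0.02 per entry.

## Interventions and economics

Three one-year lifestyle programs ship as presets, differing in the
proportional BMI reduction among achievers, the achievement rate, and
the per-person cost:

| preset     | reduction | achievement | cost/person |
|------------|-----------|-------------|-------------|
| `dpp`      | 7%        | 38.0%       | $1,400      |
| `dpp_ymca` | 5%        | 32.4%       | $346        |
| `help_pd`  | 5%        | 58.5%       | $452        |

Cost-effectiveness uses two exact identities: aversion savings equal
averted diabetes cases times the per-case benefit (default $85,200, the
lifetime medical cost associated with one diabetes case, the constant
implied by published 10-year aversion-savings figures), and total
savings equal aversion savings minus the intervention cost. The program
cost falls in year 0 and is never discounted; an optional
`discount_rate` discounts the per-year averted cases. Agent counts are
rescaled to persons by the scenario's `agent_scale` (default: a
234-million adult population divided by the number of agents).

**Diabetes-free survival (dfs) sign convention.** For each agent present
in both arms: if both arms develop diabetes, the gain is intervention
onset year minus control onset year (postponement is positive); if
neither develops it, the gain is 0; if only the control arm develops at
year $t$, the gain is censored at $H - t$ for horizon $H$; if only the
intervention arm develops at year $t$, the loss $-(H - t)$ is recorded.
Agents who die before developing diabetes in either arm are excluded
from the mean.

## The default synthetic scenario

`make_default_scenario()` builds a complete self-contained scenario with
no external data. Its parameters were chosen so the simulated
epidemiology lands in the plausible U.S. adult range: annual diabetes
incidence near 1 per 100 at-risk adults and prevalence rising from about
7 to about 13 per 100 over a 40-year horizon. Risk rises multiplicatively
with age band and BMI category and is slightly higher for men; reversion
from prediabetes declines with age; the life table is Gompertz-like with
a 1.6× male excess; entrants arrive at 1.8% of the initial cohort per
year, mostly normoglycemic. These defaults are fixed study conditions,
not tuning knobs.

```{r}
scn <- make_default_scenario(seed = 1, n_agents = 20000)
pr <- paired_run(scn, intervention_preset("help_pd"),
                 horizon = 15, n_agents = 20000, seed = 1)
glance(pr)
```

## Problem sizes and performance

A paired 15-year run with 50,000 agents completes in roughly two
seconds; the property-based test battery (30 master seeds × three
interventions at that size) runs in about two minutes. TPM estimation on
a 5,000-subject, 4-visit panel takes well under a minute.

## Limitations

* Glycemic state is ternary; HbA1c and fasting glucose are not modeled
  continuously, so partial progression within a state is invisible.
* Diabetes is strictly absorbing; remission through intervention or
  surgery is out of scope.
* Interventions act only through BMI and only in the first simulated
  year; behavioral persistence beyond the optional one-year rebound is
  not modeled.
* The economic module is an accounting identity on averted cases; it is
  not a health-economic model with QALYs or payer perspectives.
* The default synthetic scenario is calibrated to plausible aggregate
  ranges, not fitted to any cohort; conclusions about specific
  populations require user-supplied transition, mortality, and drift
  inputs.
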