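---
title: "Methods: a Markov cost-effectiveness model of bariatric surgery for T2DM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cost-effectiveness model of bariatric surgery for T2DM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baricea)
```

## Scope and rationale

`baricea` implements a payer-perspective cost-utility comparison of
bariatric (gastric bypass) surgery against conventional medication therapy
for obese patients with recently diagnosed type 2 diabetes. The patient
data behind such analyses are typically restricted, so the package pairs
the decision model with a synthetic-cohort generator and a
propensity-score-matching stage: every step of the analysis — from
"observational cohort with confounded treatment assignment" to
"probability the intervention is cost-effective" — can be exercised,
tested and audited on simulated data with the published summary structure.

## The Markov cohort model

Three mutually exclusive health states: **T2DM remission** (fasting
glucose and HbA1c controlled without medication), **T2DM**, and **death**
(absorbing). The cycle length is one year and the default horizon is 40
transition cycles, matching the remaining life expectancy of a cohort in
its early forties.

Two conventions matter enough to state precisely:

* **Cycle indexing.** The trace has `horizon + 1` rows, labelled cycle 0
  through cycle 40. Cycle 0 is the treatment year: it carries the observed
  end-of-follow-up outcome distribution of the arm (the fraction already
  in remission) and the strategy's initial cost, and it is not discounted.
  Cycles 1–40 are generated by the transition matrix. We validated this
  convention against the alternative (no cycle-0 row, 40 rows total): only
  the 41-row form reproduces the published undiscounted totals — the
  40-row form understates undiscounted QALYs by ≈1.9% and discounted costs
  by ≈0.3% — and only it places the cumulative-cost crossover at the cycle
  index the source reports with the cumulative values it prints.
* **Discounting.** Cost and QALY contributions at cycle *t* ≥ 1 are
  divided by (1 + r)^*t* with r = 5%/year, so the first year is
  undiscounted ("costs and outcomes beyond the first year are
  discounted"). The alternative exponent *t* + 1 is available via
  `accrue(discount_exponent = "cycle_plus_one")` but does not reproduce
  the published totals. No half-cycle correction is applied; adding one is
  likewise incompatible with the published totals.

The transition matrix (`transition_matrix()`) allows remission → T2DM
relapse and state-specific mortality; T2DM → remission after cycle 0 is
zero by default, because sustained remission is only observed during the
initial treatment year and no re-remission probability is published. A
nonzero `p_reremission` argument exists for scenario analyses.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `cost_surgery_initial` | 46,404.41 | CNY | surgery + first-year care, cycle 0 |
| `cost_surgery_cycle` | 2,766.41 | CNY/yr | surgery-arm maintenance, cycles ≥ 1 |
| `cost_medication_initial` | 12,581.46 | CNY | medication, first year |
| `cost_medication_cycle` | 7,674.24 | CNY/yr | medication maintenance |
| `u_remission` | 0.95 | — | utility, remission state |
| `u_t2dm` | 0.77 | — | utility, T2DM state |
| `p_relapse` | 0.0025 | /yr | remission → T2DM |
| `mu_remission` | 0.0062 | /yr | mortality, remission state |
| `mu_t2dm` | 0.0204 | /yr | mortality, T2DM state |
| `init_remission_surgery` | 22/41 | — | cycle-0 remission share, surgery |
| `init_remission_medication` | 1/41 | — | cycle-0 remission share, medication |
| `rate` | 0.05 | /yr | discount rate |
| `wtp` | 193,932 | CNY/QALY | willingness-to-pay (3× GDP per capita) |

Costs accrue only to alive patients; death carries neither cost nor
utility. The initial cost applies to the whole arm at cycle 0 regardless
of state, since every patient received the intervention. The remission
state's mortality equals non-diabetic population mortality — the model's
assumption that remission restores a healthy person's mortality risk.

### Mortality decomposition

National statistics publish one all-cause mortality rate μ for the whole
population. With diabetes prevalence *p* and a diabetic/non-diabetic
relative mortality ratio RR, mixing gives the non-diabetic rate
μ_ND = μ / (1 − *p* + *p*·RR), and the deaths-accounting identity
μ·b = μ_ND·(b − a) + μ_D·a over a population of b with a diabetic members
gives the diabetic rate μ_D (`mu_nondiabetic()`, `mu_diabetic()`; the
identity holds to machine precision by construction, and μ_D = RR·μ_ND
whenever a/b = *p*). RR itself is assembled by `weighted_rr()`: per-sex
unweighted means of the age-band RRs over a configurable window, combined
by the cohort's sex ratio. The window is configurable because the source
material quotes both 40–84 and 42–82 years; the package takes it as an
argument rather than guessing. The shipped defaults use the published
per-state annual values (0.0062, 0.0204) directly rather than re-deriving
them, since the national μ, b and a behind them are not printed.
`rate_to_probability()` defaults to the identity conversion — the source
tables label annual values as probabilities and the model consumes them
verbatim — with the actuarial 1 − exp(−rate·cycle) available as an option.

## Synthetic cohorts and matching

`generate_cohort()` emulates the published unmatched cohort: 134 surgery
and 81 medication patients; sex, age, BMI, fasting plasma glucose and
HbA1c drawn as independent normals at each arm's published mean ± SD
(only marginal summaries are published, so no correlation structure is
imposed; a floor at 1% of the mean, enforced by redraw, keeps physiologic
values positive); 2-year remission at 71/134 and 4/81; 2-year mortality 0,
as observed. Because the two arms' covariate summaries differ, cohorts
drawn from the default spec reproduce the published pre-matching imbalance
directly. Alternatively, nonzero log-odds confounding coefficients switch
generation to a pooled covariate population with logistic treatment
assignment, filled to the arm sizes by rejection — the mode used to verify
that `fit_propensity()` recovers known assignment coefficients.

What the generator does **not** emulate: covariate correlations, skewed or
heavy-tailed laboratory values, dropout, medication heterogeneity, and
eligibility rules. Passing tests therefore demonstrate the correctness of
the pipeline's logic and statistics on data *of the published shape*, not
robustness to real-data pathologies.

Matching is greedy 1:1 nearest-neighbour without replacement within a
calliper of 0.03 on the propensity (probability) scale. The source does
not name the calliper's scale; 0.03 in probability units is the common
reading, and a logit-scale × SD calliper is available
(`match_caliper(scale = "logit_sd")`). The greedy visiting order —
descending propensity score, ties broken by patient id — is likewise not
specified upstream; a documented deterministic order is required for
reproducibility, and tests verify the result is invariant to id
relabelling and agrees with an exhaustive reference matcher. Unmatched
patients are discarded. By default the matched cohort informs balance
reporting only; the configuration flag `psm.use_matched_init` lets the
matched arms' observed remission shares drive the Markov initial
distribution instead of the published 22/41 and 1/41.

## Sensitivity analyses

**One-way (tornado).** Each parameter moves to its low and high bound with
the rest at base. Bounds default to the published ranges, which are ±20%
of base for costs and probabilities, with the remission utility's upper
bound clamped to 1.0 (0.95 × 1.2 would exceed the utility scale). Two
outcome metrics are computed per bound: the signed ICER — the axis of the
classical tornado figure, well defined here because surgery remains
dominant across every bound — and incremental net monetary benefit at the
WTP threshold, which remains sign-stable should a user's scenario break
dominance. Entries are ranked by ICER spread by default
(`one_way(metric = "inmb")` switches); under the ICER ranking the
remission-state utility is the most influential parameter, followed by the
medication cycle cost and the T2DM utility. Under the INMB ranking the two
utilities swap, a direct consequence of the remission utility's clamped
upper bound.

**Probabilistic (PSA).** A 1,000-draw second-order Monte Carlo samples
gamma distributions for the four costs and beta distributions for the two
utilities and three transition probabilities, independently (no
correlation information is published). Published ranges carry no
variances, so each range is treated as a 95% interval,
SD = (high − low)/3.92, and hyperparameters are moment-matched
(gamma: shape = m²/SD²; beta: method of moments) — standard
health-economics practice. The discount rate is varied in the tornado but
not sampled in the PSA; the initial remission shares can be added to the
sampled set via `param_specs()`. Draws producing an invalid model are
rejected, redrawn and counted (none occur at the default calibration).

At this calibration the probability that surgery is cost-effective at the
threshold is ≈99.9% rather than a literal 100%: with utilities sampled
independently, roughly 1–2 draws per 1,000 put the remission utility far
enough below the T2DM utility to flip the sign of the QALY increment.
Observing a clean 100% over a single 1,000-draw run is entirely consistent
with that rate, so the acceptance tests assert the ≥95% band at several
seeds instead of exact unanimity. The acceptability curve is
correspondingly flat at ≈1 across the 0–400,000 CNY/QALY grid (steps of
10,000).

## Numerical choices and degenerate inputs

* Trace conservation is enforced implicitly (rows sum to 1 within 1e−12 in
  tests); accumulation uses plain `cumsum` over ≤ 41 cycles, where drift
  is far below reporting precision.
* `initial_distribution()` rejects fractions that do not sum to 1 within
  1e−9; `transition_matrix()` rejects row sums exceeding 1.
* Logistic fits abort on rank deficiency, non-convergence, or fitted
  probabilities within 1e−8 of the {0, 1} boundary (perfect separation)
  rather than returning diverged coefficients.
* A zero calliper (with distinct scores) legitimately yields an empty
  matching; balance reports then flag the after-matching section as
  undefined instead of erroring.
* Zero-variance sensitivity ranges collapse draws to the base value and
  tornado spreads to 0; a beta SD exceeding its support raises an error
  naming the parameter.

## Problem sizes

The test suite runs the full 41-row deterministic model (milliseconds),
Monte-Carlo checks sized for stable verdicts at small cost: a 10⁵-patient
microsimulation against the cohort trace, coefficient recovery on a
5,000-patient confounded cohort, 100–200 replicate cohorts for balance
improvement and nominal-rate checks, and PSA runs of 250–1,000 draws.
These sizes put Monte-Carlo standard errors well inside the asserted
bands (assertions use 3–4 SE).

## Known limitations

* No obesity-comorbidity states, no age-dependent transition
  probabilities within the run, and no tunnel states — the model inherits
  the published three-state structure.
* Re-remission after the first year is off by default; if real-world
  re-remission is material, the model understates the medication arm.
* The synthetic generator's independence assumptions (covariates,
  PSA parameters) are simplifications; correlated draws would widen or
  narrow uncertainty in ways the published material cannot calibrate.
* Costs are 2015 CNY throughout; no currency conversion or inflation
  adjustment is provided.
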