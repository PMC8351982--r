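---
title: "A Markov cohort model for recanalization-reducing coiling adjuncts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for recanalization-reducing coiling adjuncts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilcea)
```

## The decision problem

Endovascular coiling is the dominant treatment for unruptured
intracranial aneurysms (UIA), but coils compact over time and roughly a
quarter of treated aneurysms *recanalize* within about six years,
restoring rupture risk and driving repeat procedures. An adjunct health
technology innovation (HTI) — a stem-cell coating, an improved coil —
administered during the index procedure could reduce that recanalization
rate. `coilcea` asks the payer-perspective question: for an adjunct with
relative risk reduction (RRR) $x$ and price $y$, is standard coiling
plus the adjunct cost-effective against standard coiling alone, and what
is the largest $y$ a payer should accept at a given willingness-to-pay
threshold $\lambda$ (USD/QALY)?

Two strategy arms are compared over 60 six-month cycles (30 years) for a
cohort entering at age 45 immediately after the index coiling. Costs
(2018 USD) and QALYs are both discounted at 1.5 %/year. The comparison
is driven by a 25-variable parameter table (transition probabilities,
costs, utilities) bundled with the package; every stochastic variable
carries a published mean and standard error plus one-way sensitivity
bounds.

## Health-state dynamics

States are `coiled(i, status, a)`, `unsecured(i, status)`, a one-cycle
aSAH (aneurysmal subarachnoid hemorrhage) tunnel `asah(i, status)`, and
absorbing `dead`, where $i \in \{1..4\}$ counts coiling procedures,
`status` is mRS 0 / mRS 1–2 / mRS 3–5 (functional status, which can only
worsen), and $a$ counts cycles since the most recent procedure.

The central structural reading is that the quoted recanalization
probability (0.244 *per 6 years*, per procedure) is the risk the coil
compacts during the six years following the procedure, not a lifelong
constant hazard: a lifelong reading would imply ~75 % of patients
recanalize within the horizon, which is inconsistent with the quoted
~25 % per-procedure rate. Coiled states therefore carry the
recanalization hazard only while $a$ is inside the 6-year window
(`recan_window_years`, configurable; `Inf` recovers the lifelong
reading). The adjunct multiplies the index coil's recanalization hazard
by $(1-x)$; it is administered only at the index procedure, so only
`i = 1` is protected. By default later coils do not re-enter the window
(`recan_later_procedures = FALSE`); de novo aneurysm formation
(0.6 %/year) is always active and is pooled into the same unsecured
state.

Unsecured patients face rupture (1.4 %/year), carry the untreated-
aneurysm disutility (−0.07), and are retreated. The quoted retreatment
probability (0.091 per 6 years, 166/1699) is *marginal over all coiled
patients*, while recanalization is 0.244 (321/1316); conditional on
harbouring an untreated aneurysm the retreatment probability is their
ratio (≈ 0.37 per 6 years). `retreat_conditional = FALSE` applies the
marginal figure directly instead. Retreatment is a full coiling
procedure: complication split (mild disability 4.8 %, moderate-severe
2.2 %, death 2.0 %), matching procedure costs, ratcheted status, and
$i+1$. After the fourth procedure patients remain unsecured
indefinitely.

Rupture enters the aSAH tunnel for exactly one cycle: utility 0.41 for
that half-year, expected hospital cost $(1-p_{8})\,\$93{,}440$ (12.4 %
die before reaching hospital and incur no hospital care), then death
(pre-hospital or in-hospital) or treatment to `coiled(i+1)` with status
ratcheted against the aSAH outcome; survivors' coiling is part of the
admission, so no separate procedure cost is charged.

Background all-cause mortality applies in every alive state from a
bundled abridged period life table (synthetic, both-sex, US-like 2018
level, 5-year bands; survival 45→75 ≈ 0.71). It is material over a
30-year horizon starting at age 45 and is on by default
(`background_mortality = FALSE` disables it).

## Numerical conventions

* **Cycle conversion.** Probabilities quoted over a period are rescaled
  to the half-year cycle *linearly* ($p \cdot \text{cycle}/\text{period}$),
  the spreadsheet convention the published results reflect;
  `probability_conversion = "constant_hazard"` switches to
  $1-(1-p)^{c/t}$ (the two differ by ≤ ~13 % here). The exported
  [per_cycle_probability()] implements the constant-hazard form.
* **Competing risks.** Within a cycle, competing per-cycle
  probabilities are converted to hazards, the total transition
  probability $1-e^{-\sum h}$ is allocated proportionally to each
  hazard, and the residual stays in state — no residual can go
  negative, so no draw is infeasible through this route.
* **Accrual and discounting.** No half-cycle correction: state costs
  (annual care cost × cycle length) and utilities accrue on the
  occupancy at cycle start with that cycle's factor
  $(1+r)^{-k/2}$; event costs on transitions (retreatment procedures)
  use the arrival cycle's factor. The index procedure's complication
  split, its cost, and the adjunct price are charged undiscounted at
  cycle 0.
* **Age bands.** The mRS 0 utility is age-banded (0.87 / 0.85 / 0.86 /
  0.84 for 45–54 / 55–64 / 65–74 / 75+, half-open bands). One value is
  drawn per iteration and all bands move with it at the printed
  offsets, preserving the non-monotone published pattern.

## Parameter distributions

Beta and Gamma variables are moment-matched to the printed mean and SE
(`beta_from_moments()`, `gamma_from_moments()`); the printed moments are
authoritative over the raw event counts, several of which are
inconsistent with the printed values because multiple sources were
pooled. The untreated-aneurysm disutility is a negative decrement whose
magnitude is Beta with mean 0.07 and SE 0.04082.

"Truncated ordered normal" groups (procedure costs, care costs,
utilities) are drawn from normals truncated to natural bounds (costs
≥ 0, utilities in [0, 1]) with the *location parameter solved so the
truncated mean equals the printed mean* — important for the
fatal-complication cost, whose SE (58,090) is comparable to its mean
(65,336), so naive truncation would inflate the mean by ~20 %. Group
ordering is imposed comonotonically: one shared uniform is pushed
through each member's inverse CDF, which preserves every printed
marginal exactly and orders the draw wherever the quantile curves do
not cross (always, in practice, for the utility and care-cost groups;
the procedure-cost group can invert deep in the lower tail, reflecting
the huge SE of the fatal-complication cost). A rejection-based
alternative (`method = "rejection"`) guarantees ordering in every draw
but conditions the marginals of strongly overlapping groups away from
their printed means, which is why it is not the PSA default.

Joint draws that push an outcome split past probability 1 (procedural
or aSAH outcomes) are rejected and redrawn, preserving marginals; the
redraw count is reported and a warning is raised past 1 %.

## The analysis pipeline

`run_psa()` propagates `n` joint draws through both arms with common
random numbers (the same draw feeds both arms, so per-iteration
increments are noise-free in the shared parameters). `replicate_psa()`
repeats the PSA on independent substreams — the base case uses 7,000
iterations per replicate — and reports each statistic's replicate mean
and 2.5th/97.5th percentiles as the 95 % credible interval. From the
per-iteration records: the ICER (ratio of mean increments), CEAC
(probability $\lambda\Delta E-\Delta C>0$; ties count against the
adjunct), and per-person EVPI
($E[\max_s \mathrm{NMB}_s]-\max_s E[\mathrm{NMB}_s]$), scaled to the
population by the undiscounted product 15,925 procedures/year × 10
years.

The **price-elasticity sweep** fixes the RRR at each of 101 values
(0 to 1 in 1 % steps), excludes the price from costs, and computes the
maximum cost-effective price as the largest $p$ keeping the probability
of cost-effectiveness ≥ 0.5. Because the price enters the incremental
cost additively, once, undiscounted, this is the median of
$\lambda\Delta E-\Delta C_0$, floored at 0 — the price-bisection
formulation is retained as a test oracle. One set of draws is shared
across the grid (the standard arm is propagated once), so the curve is
smooth, and a zero-intercept least-squares line
($\hat\beta=\sum xy/\sum x^2$) summarizes it.

**EVPPI** uses brute-force two-level nesting (outer draws of the focal
variable, inner PSAs conditional on it; 500 × 500 by default) rather
than regression approximations, because one inner PSA costs
milliseconds in the vectorized engine; one nested simulation is shared
across thresholds. The **tornado** analysis is probabilistic one-way:
each variable in turn is fixed at its printed sensitivity bounds
(±2 SE unless overridden in the table) while all others stay
stochastic, and the full PSA is rerun at each bound. Fixing a grouped
variable bypasses the ordering constraint for that variable, which is
the intended reading of a one-way perturbation. **Scenario analyses**
redraw the RRR from normals bounded to [0, 1] with mean (SD) 10 (2),
30 (5), 50 (15) %, price unchanged.

## Verification layer

`simulate_patients()` is an independent individual-level implementation
of the same dynamics: per-patient procedure counts, status, and
cycles-since-procedure, stepped by sampling rather than expectation
propagation, sharing no propagation code with the cohort engine.
`cohort_vs_microsim_check()` compares both arms' discounted cost and
QALY and flags deviations beyond 3 Monte Carlo standard errors; the
test suite runs it at the published means and on random tables from
`random_parameter_table()`, which emulates the bundled table's
structure (families, groups, quoted periods) with randomized,
family-feasible moments. The hospital cost of an aSAH admission enters
both engines as its expectation over pre-hospital survival, so the
cross-check is exact in the mean.

What the synthetic layer does *not* emulate: correlations between
tabled variables beyond the ordered groups, patient-level heterogeneity
in entry age or aneurysm morphology, and time trends in care costs. A
green suite therefore shows internal consistency of the engines and
faithfulness to the stated distributions — not external validity of the
parameter table itself.

## Problem sizes and runtime

The vectorized engine propagates a 7,000-iteration two-arm PSA in a few
seconds, so the shipped analyses use: 7,000 × 20 replicates for the
base case (the credible intervals stabilize well before that), 2,000
iterations per elasticity grid point, 7,000 for each scenario and
discount-rate run, and 500 × 500 for EVPPI. Tests use smaller sizes
chosen so each property still has discriminating power at 3-SE
tolerances.

## Design choices on open structural questions

The published model's detailed state diagram and simulation appendix
are not available, so several structural choices were fixed here and
are exposed as configuration options rather than hard-coded: the
recanalization window and its restriction to the index coil, the
conditional reading of the retreatment probability, linear cycle
conversion, background mortality from a synthetic life table, and
expected (rather than sampled) pre-hospital attrition of the aSAH
hospital cost. With these defaults the model reproduces the published
base case (means-level incremental QALY ≈ 0.151 at an expected RRR of
50 %, ICER within the published credible interval) and the published
discount-rate scenario ICERs to within ~2 %; the alternatives each
moved at least one of those quantities far outside its published
interval. The known residual: the published 10-year population EVPPI
for the recanalization probability at $50,000/QALY (~$113 M) is about
1.8× what this model computes (~$63 M); back-calculation from the
published base-case increments supports the smaller value, so the
package reports its computed number rather than calibrating toward the
printed one.

## Limitations

Single entry age and payer perspective; no repeat adjunct
administration at retreatment; no aneurysm-morphology or rupture-risk
heterogeneity; the bundled life table is representative rather than
official; and all Table values are taken as given rather than
re-derived from their sources.
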