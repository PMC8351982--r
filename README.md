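# coilcea

Cost-effectiveness of recanalization-reducing adjuncts to endovascular
coiling of unruptured intracranial aneurysms (UIA).

Coiled aneurysms recanalize — the coil mass compacts and blood re-enters
the aneurysm — in roughly a quarter of patients within about six years
of the procedure, restoring rupture risk and driving repeat treatments.
An adjunct health technology innovation (HTI, e.g. a mesenchymal
stem-cell coating) administered during the index coiling could reduce
that rate. `coilcea` implements a probabilistic Markov cohort model,
from the healthcare-payer perspective, that compares standard coiling
against standard coiling plus such an adjunct, and asks at what price
and efficacy the adjunct is worth paying for.

## The model in brief

A cohort enters at age 45 immediately after the index coiling and is
followed for 60 six-month cycles (30 years). States track the number of
coiling procedures *i* = 1–4, functional status (mRS 0 / 1–2 / 3–5,
ratcheted — it can only worsen), and time since the last procedure.
Each coil carries a recanalization risk of 0.244 over the 6 years
following its placement; the adjunct multiplies the index coil's risk
by (1 − *x*), where *x* is its relative risk reduction (RRR). Untreated
(recanalized or de novo) aneurysms carry a utility decrement of −0.07,
an annual rupture probability of 1.4 % (rupture: 93 % of survivors'
hospital costs, death or disability per published aSAH outcome splits),
and are retreated at the published rate. Costs (2018 USD) and QALYs are
discounted at 1.5 %/year. All 25 model parameters ship as a CSV with
printed means, standard errors and distribution families
(moment-matched Beta/Gamma, mean-preserving truncated normals with
ordered groups); background mortality comes from a bundled synthetic
abridged life table.

On top of the cohort engine the package provides:

* **PSA** — `run_psa()`, `replicate_psa()`: Monte Carlo propagation
  with common random numbers across arms; replicate-based 95 %
  credible intervals; `convergence_profile()`.
* **Decision analytics** — `icer()`, `ceac_point()`,
  `evpi_per_person()`, `evppi()` (nested two-level Monte Carlo),
  `scale_to_population()` (15,925 US procedures/year × 10 years),
  `tornado_one_way()`, `discount_rate_scenarios()`, `scenario_rrr()`.
* **Price-elasticity analysis** — `elasticity_curve()`,
  `max_price_at()`: the maximum cost-effective adjunct price
  *y* ≈ β·*x* as a through-origin line in the RRR at a given
  willingness-to-pay threshold λ, where the maximum price at fixed *x*
  is the median of λ·ΔQALY − ΔCost (price excluded), floored at 0.
* **Verification** — `simulate_patients()`, an independent patient-level
  microsimulation of the same dynamics, `cohort_vs_microsim_check()`,
  and `random_parameter_table()` for property-style testing.
* **Pipelines** — `load_config()` (YAML), `run_analysis()` and
  `write_outputs()` for end-to-end runs with manifests.

## Worked example

```r
library(coilcea)
specs <- load_parameter_table()        # the bundled 25-variable table
cfg   <- model_config()                # base case: $10,000 adjunct, 1.5%/y
psa   <- run_psa(specs, hti_efficacy("uniform01"), cfg, 2000, seed = 1)
cea_summary(psa, cfg)
```

```
Mean discounted cost: HTI $308206 | standard $301166
Mean discounted QALY: HTI 18.042 | standard 17.891
ICER: $46571 per QALY
CEAC:
 threshold probability
     50000      0.4760
    100000      0.6965
    150000      0.7850
EVPI:
 threshold per_person population
     50000   2595.253  413293963
    100000   1502.505  239273855
    150000   1049.978  167209036
```

Read: with an adjunct of unknown efficacy (RRR uniform on [0, 1],
expectation 50 %) priced at $10,000, the extra $7,040 buys 0.151 QALYs
on average — about $46,600 per QALY, borderline at a $50,000/QALY
threshold (probability cost-effective 0.48) and clearly worthwhile at
$100,000+. Eliminating all parameter uncertainty would be worth ~$413 M
to the US system over 10 years at λ = $50,000.

The price-elasticity view inverts the question — what is the most a
payer should pay for a given efficacy:

```r
ec <- elasticity_curve(specs, cfg, lambda = 50000,
                       n_iterations = 2000, seed = 1)
ec$fitted_slope     # ~ 20,600 USD per unit RRR: y <= slope * x is
                    # the payer's maximum cost-effective price
```

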