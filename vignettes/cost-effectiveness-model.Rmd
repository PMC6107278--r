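---
title: "A cost-utility model for urine-biomarker triage in suspected bladder cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cost-utility model for urine-biomarker triage in suspected bladder cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triagecea)
```

## The decision problem

Patients presenting with haematuria are investigated for bladder cancer.
The reference pathway sends every presenter to flexible cystoscopy — an
invasive, uncomfortable and relatively expensive endoscopy. `triagecea`
models an alternative pathway in which a non-invasive urine-biomarker
classifier (the DCRSHP test) is applied first and only triage-positive
patients proceed to cystoscopy; a case counts as detected only if both
tests are positive (a series rule, with the two tests treated as
conditionally independent given disease status).

The package evaluates the triage pathway against cystoscopy-for-all as a
cost-utility analysis from a health-care-provider perspective: a
decision tree splits the presenting cohort into true/false
positives/negatives, and a Markov cohort model follows every patient for
five years in six-month cycles, accumulating discounted costs, QALYs and
life years. Because the test's price is not yet set, the analysis is
organised around *early* cost-effectiveness questions: the maximum price
at which triage stays cost-effective, how the answer moves with disease
prevalence, and how much of the decision uncertainty is attributable to
which parameters.

## Model structure

**Decision tree.** With prevalence $p$ and sensitivities/specificities
$(se_d, sp_d)$ for the triage test and $(se_c, sp_c)$ for cystoscopy,
the triage arm has $tp = p\,se_d se_c$,
$fp = (1-p)(1-sp_d)(1-sp_c)$, and a referred fraction
$p\,se_d + (1-p)(1-sp_d)$; the cystoscopy arm follows the single-test
arithmetic. Test positives receive a diagnostic TURBT (false positives
with negative histology return to the well state). Testing-phase costs
and disutilities fall at time zero and are not discounted.

**Markov model.** Thirteen states: well; five diagnosed cancer states —
low-risk NMIBC, high-risk NMIBC on BCG, high-risk NMIBC post-cystectomy,
MIBC post-cystectomy, metastasis — their five undiagnosed mirrors for
the false-negative track; and two absorbing death states
(bladder-cancer death vs other-cause/procedural death). Diagnosed
patients enter in the observed stage mix at presentation
(105/47/13/14/13 out of 192). Six-month transition probabilities cover
recurrence (LR 0.0638, HR 0.1393; 9/52 of recurrences convert to the
cystectomy pathway), progression (HR-BCG to MIBC 0.030 and to metastasis
0.010, post-cystectomy 0.030, MIBC 0.0771 within five years),
cancer death (0.0048 in remission states, 0.0497 for MIBC, 0.236 in
metastasis) and procedure mortality (TURBT 0.008, cystectomy 96/4484).

**False-negative track.** Missed cases progress at a relative risk of
2.56 applied to progression and cancer-death probabilities (truncated
below 1 when sampled). Haematuria persists, so missed cases are found
over time: cumulatively 50% by one year, 75% by two, all thereafter.
On the six-month grid this is a per-cycle conditional detection
probability of $1-\sqrt{0.5}\approx0.293$ in cycles 1–4 and 1 from
cycle 5. Detected patients receive a TURBT and the entry treatment
bundle of their counterpart state (BCG induction; cystectomy with its
mortality, complication and impotence consequences; chemotherapy for
MIBC; palliative care on metastasis entry). We apply the full entry
bundle because entering a post-cystectomy state without the surgery
would be incoherent clinically and would under-count the cost of late
diagnosis.

**Rewards.** Cycle rewards use half-cycle-corrected occupancy (the mean
of start- and end-of-cycle vectors) and are discounted at 3.5% per year
at the cycle midpoint, a timing consistent with the occupancy averaging;
the deathless discounted life-year total therefore reduces to the
mid-cycle annuity $\sum_{k=1}^{10} 0.5 \times 1.035^{-(k-0.5)/2}$, which
the tests match to $10^{-10}$. Surveillance and treatment schedules
(cystoscopies, CT scans, BCG vials) are clocked from *state entry*, not
model time: the engine decomposes the occupancy of each schedule-bearing
state by tenure, so a patient diagnosed late still receives the full
three-year BCG course and surveillance sequence. Schedule-to-cycle
roundings are visible constants in `bc_parameters()$schedules`.

**Competing risks.** Disease-specific transitions are applied first;
age-specific all-cause mortality then applies to the residual in-state
probability only. This preserves the printed disease probabilities
exactly and never rescales a row; a parameter set whose row exceeds 1 is
an error naming the state (in the PSA such rare joint draws are redrawn
and counted).

## Utility conventions

The utility table gives decrements and a handful of state utilities but
leaves the standing utility of diagnosed NMIBC open. We resolved the
open conventions against the published base-case table, which is the
only place the source model's conventions are observable:

* **Cancer-state utility 0.78** (`u_cancer`). The published QALY-to-LYG
  ratio (4.3139/4.4377 = 0.972 for the cystoscopy arm) implies an
  average utility deficit of about 0.028 across the cohort — almost
  exactly prevalence × (1 − 0.78). The only cancer health-state utility
  in the source table is 0.78, and we apply it to the NMIBC states and
  the undiagnosed mirrors alike. It is one parameter, sampled once in
  the PSA, so no artificial utility gap between diagnosed and
  undiagnosed disease is created.
* **Untreated metastasis at 0.3.** Undiagnosed metastatic patients
  receive no chemotherapy and therefore take the
  unresponsive-to-chemotherapy utility rather than the
  response-weighted mixture (0.436) used for treated metastasis.
* **Post-cystectomy states** stand at 0.96, multiplied by 0.91 for the
  impotent fraction (0.59) — a multiplicative, permanent combination.
* **Cystoscopy disutility** is the 0.997 six-month factor per
  procedure, i.e. 0.0015 QALY per scope — about half a day of perfect
  health, applied to the diagnostic scope and to every surveillance
  scope.
* **The well state is 1.0**; decrements are all relative.

Event decrements are duration-scaled: TURBT 0.1 over 7 days, BCG
induction 0.02 over 6 weeks plus a 0.286-probability complication of
0.2 over six months, cystectomy (1 − 0.8) over 60 days plus a
0.267-probability complication of 0.3 over 60 days, chemotherapy 0.36
over 103 days per course.

## Cost conventions

Costs are GBP (2014): cystectomy £9,816, TURBT £2,435, flexible
cystoscopy £537, CT £395, BCG £71.61/vial (six vials per cycle for the
first three years), cisplatin £50.22/vial (three per course;
responsive metastatic patients receive a course every six months). The
palliative-care tariff (£160.46, a same-day attendance) is charged once
on entry to metastasis: although metastatic patients receive 135 days of
palliative care, charging the day tariff for all 135 days
(≈£21,700/patient) is irreconcilable with the published per-patient
cost totals, while a single attendance reproduces them;
`charge_palliative_per_day = TRUE` restores the literal per-day
reading. Procedural mortality applies to procedures within the Markov
phase; the time-zero diagnostic TURBT carries cost and disutility but no
mortality (the time-zero cystectomy keeps its mortality, as it
determines state entry) — with tree-stage TURBT deaths the model cannot
reproduce the published prevalence-crossover behaviour.

## The all-cause mortality fixture

National-statistics mortality enters only as "variable by age". The
package ships a synthetic Gompertz life table (`make_life_table()`):
sex-specific hazards $h_0 e^{0.095(a-60)}$ integrated over six-month
intervals and mixed 0.796 male / 0.204 female. The baselines
(male 0.0087, female 0.0056 annual at age 60) match the magnitude of
the UK interim life tables around the costing year, giving a mixed
six-month probability near 0.004 at 60. This fixture reproduces level
and slope, not cohort or calendar-year detail; results are insensitive
to such detail over a five-year horizon at age 60 because
bladder-cancer-specific mortality dominates in the disease states.

## Probabilistic sensitivity analysis

Sampled distributions follow the families the analysis prescribes:

* Beta(successes, failures) for count-backed probabilities (test
  accuracies, pooled prevalence 871/5857, TURBT and cystectomy
  mortality, recurrence-to-cystectomy 9/43); the mean equals the
  observed proportion exactly (no pseudo-counts; switchable).
* Beta by method of moments with SE $=(U-L)/(2\times1.96)$ for
  range-only utilities, event probabilities and the recurrence
  probabilities (whose CIs are printed without counts).
* Log-normal (method of moments on the magnitude) for utility
  decrements; log-normal with natural-scale mean 2.56 and SE 1,
  truncated at 1, for the untreated relative risk.
* Dirichlet over the printed counts for the diagnosis split.
* Uniform(£50, £620) for the test price — the only reading under which
  the stated price range enters the PSA; a fixed price is a switch.
* Costs, and six-month probabilities derived from survival times rather
  than direct counts, are held fixed (no usable uncertainty is printed
  at the six-month scale).

CEAC ties contribute 0.5 to each strategy. The threshold price is
closed-form (the price enters the triage arm's cost affinely with
slope 1, so the threshold equals incremental NMB at price zero) and is
verified against bisection to £0.01. Sweep crossings are linearly
interpolated on a 0.005 prevalence grid.

## Value of information

EVPI is the mean-max identity on the PSA net-benefit sample. EVPPI uses
the nonparametric regression estimator: per strategy, net benefit is
regressed on the parameter subset with additive penalised splines
(`mgcv::gam`), basis dimension capped near $\sqrt n$ for small subsets
and 4 per term for larger ones (columns with too few distinct values
enter linearly); EVPPI is the mean-max minus max-mean of the fitted
values, floored at zero. Because net benefit is deterministic given all
sampled parameters, EVPPI of the full set approaches EVPI, which the
tests check to 5%; a linear-net-benefit toy is checked against its
closed form to 2%.

## Problem sizes and numerical choices

The test suite runs the deterministic pipeline at full size (10 cycles,
13 states), the PSA at 10,000 draws for the acceptance check and 1,500
draws for the VOI properties, and validates the cohort engine against
an independently written per-patient microsimulation (100,000 patients,
seeded) within three Monte-Carlo standard errors on cost, QALYs and
life years. Mass conservation is enforced at $10^{-9}$ per cycle and
transition rows at $10^{-10}$.

## Known limitations

* The ICER at the published price sits on a knife edge (an incremental
  0.00004 QALYs), so its reproduction depends on downstream-cost
  conventions that are not printed; this package's reconstruction puts
  the triage arm slightly cheaper and very slightly less effective at
  the pooled prevalence, with the same policy conclusions (threshold
  price ≈ £465–510, effectiveness crossover ≈ 0.11–0.14).
* Tests are assumed conditionally independent given disease status; no
  correlation structure is published.
* No upper-tract imaging or cytology arm, no test refusal, no
  radiotherapy or palliative TURBT, no individual-level heterogeneity
  beyond the sex-weighted life table, and no currency inflation engine.
* The utility set was not elicited with a validated instrument in the
  source material; the PSA spreads reflect that, and QALY-based
  conclusions should be read alongside the life-year results.
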