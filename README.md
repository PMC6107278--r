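# triagecea

Early cost-utility analysis of a urine-biomarker triage test (the
DCRSHP classifier) used ahead of flexible cystoscopy in the diagnostic
work-up of haematuria patients suspected of bladder cancer.

Cystoscopy is the gold-standard test but is invasive, uncomfortable and
costs over £500 per procedure. A non-invasive urine test applied first
— with only triage-positive patients referred on to cystoscopy — could
spare many patients an invasive procedure at the cost of missing some
cancers. Whether that trade is worth making, and at what unit price for
the new test, is a health-economics question. `triagecea` answers it
with:

* a **diagnostic decision tree** (series positivity: a case is detected
  only if both tests are positive) splitting the presenting cohort into
  TP/FP/TN/FN fractions;
* a **six-month-cycle Markov cohort model** over five years with
  thirteen states: well, five treated bladder-cancer states (low-risk
  NMIBC, high-risk NMIBC on BCG, two post-cystectomy states,
  metastasis), five undiagnosed mirrors for the false-negative track
  (progressing at relative risk 2.56 and detected 50%/75%/100% by years
  1/2/beyond), and two absorbing death states — with half-cycle
  correction and 3.5% annual discounting;
* **comparative economics**: discounted cost, QALYs and life years per
  patient, ICER, and net monetary benefit
  (`NMB = QALYs × WTP − cost`);
* **deterministic sensitivity analyses**: threshold test price (closed
  form, verified by bisection), prevalence sweep with interpolated
  effectiveness crossover, two-way price-by-prevalence frontier, and a
  cystoscopy-disutility sweep;
* **probabilistic sensitivity analysis** (Beta from counts, Beta by
  method of moments from ranges with `SE = (U − L)/(2 × 1.96)`,
  log-normal decrements, Dirichlet stage mix, Uniform(£50, £620) test
  price) with CE-plane and CEAC outputs;
* **value of information**: EVPI via the mean-max identity and EVPPI
  via a nonparametric (penalised-spline) regression on the PSA sample.

All model inputs ship as a documented parameter catalogue with
provenance (`parameter_catalogue()`), overridable in code or from a
YAML config. The all-cause mortality input is a clearly-labelled
synthetic Gompertz life table calibrated to UK-magnitude rates
(`make_life_table()`).

## Worked example

```r
library(triagecea)

params <- bc_parameters()          # pooled prevalence 12.95%, price £465.48
compare_strategies(params, wtp = 20000)
#> Cost-effectiveness comparison (WTP £20,000 per QALY)
#> # A tibble: 2 × 11
#>   strategy         cost qalys life_years delta_cost delta_qalys delta_ly    icer
#>   <chr>           <dbl> <dbl>      <dbl>      <dbl>       <dbl>    <dbl>   <dbl>
#> 1 cystoscopy_only 2048.  4.31       4.43       NA     NA        NA           NA
#> 2 dcrshp_triage   2002.  4.31       4.43      -45.7   -0.000206 -0.00148 221878.
#>   dominance    nmb   wtp
#>   <chr>      <dbl> <dbl>
#> 1 <NA>      84069. 20000
#> 2 icer      84111. 20000
```

Per presenting patient over five years, the triage pathway saves about
£46 and gives up about 0.0002 QALYs — its higher NMB (84,111 vs 84,069)
says the saving outweighs the loss at £20,000/QALY. The maximum price
at which the test stays cost-effective, and the prevalence below which
it is also the *more effective* strategy:

```r
threshold_price(params, wtp = 20000)
#> [1] 507.0968
attr(prevalence_sweep(params), "crossover")
#> [1] 0.1115784
```

So at the pooled prevalence the test could be priced up to roughly
£500 and remain cost-effective, and in lower-risk subgroups
(prevalence below ~0.11) it is better on both cost and QALYs —
the case for triaging younger, lower-risk haematuria patients.

Uncertainty and information value:

```r
psa <- run_psa(params, n = 10000, seed = 1)   # price ~ Uniform(£50, £620)
glance(psa, wtp = 20000)$p_cost_effective     # probability triage is cost-effective
plot_ceac(ceac(psa))
evpi(psa, wtp = 20000)                        # £/patient of perfect information
evppi(psa, c("sens_dcrshp", "spec_dcrshp"), wtp = 20000)
```

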