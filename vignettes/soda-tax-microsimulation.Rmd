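---
title: "A microsimulation model of a soda excise tax: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A microsimulation model of a soda excise tax: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbcea)
```

## The model

`ssbcea` implements an individual-level state-transition (Markov)
microsimulation of Californian adults under a 1-cent-per-ounce
sugar-sweetened beverage (SSB) excise tax, compared with a "do nothing"
status quo. Ten mutually exclusive health states are modelled: three
weight-governed states (normal weight, overweight, obesity, assigned from
BMI), five disease states (diabetes, stroke, myocardial infarction, their
chronic sequels poststroke/post-MI, and end-stage renal disease), and
absorbing death. Stroke and MI are *tunnel states*: the acute event year
carries its own (high) cost and (low) utility, after which the individual
moves to the cheaper chronic post-event state.

The cycle length is one year and the default horizon is 20 years. A cohort
of 20,000 simulated adults stands in for the 29,247,121 Californian adults
of 2015; model counts are rescaled by 29,247,121 / 20,000 = 1,462.36.

Within each annual cycle events are applied in a fixed order:

1. **Weight update.** Every living individual gains a natural annual weight
   increment drawn uniformly from 0.45–0.91 kg/y, plus (in the tax arm) the
   tax weight effect of −0.56 kg/y. Weight is floored at 30 kg so extreme
   sensitivity-analysis draws cannot produce pathological weights.
2. **BMI reclassification.** Individuals in weight-governed states are
   reassigned among normal/overweight/obesity from BMI = weight/height²
   (overweight: 25 ≤ BMI < 30; obesity: BMI ≥ 30, both lower bounds
   inclusive). Individuals in disease states keep gaining weight but their
   state is disease-governed.
3. **One sampled transition.** At most one transition per cycle is drawn
   from the categorical distribution given by the current state's row of
   the annual transition table; the residual mass `1 − Σp` is the stay
   probability. Death is absorbing.
4. **Tunnel promotion.** An individual who spent the cycle in stroke (MI)
   and did not transition moves to poststroke (post-MI). A stroke→MI or
   MI→stroke transition restarts the other tunnel.

This ordering is a design choice — the weight update must precede BMI
reclassification, and transitions act on the updated state — and is fixed;
no alternative orderings are exposed.

Costs and utilities accrue for the state occupied *during* each cycle, with
no half-cycle correction: flows occur at cycle start, year 0 is
undiscounted, and nothing accrues after death. Both costs and QALYs are
discounted at 3%/year.

## Parameters and uncertainty

All inputs live in one YAML file
(`system.file("extdata", "soda_tax_inputs.yaml", package = "ssbcea")`):
30 annual transition probabilities, per-state annual direct medical costs
(2022 USD), EQ-5D utilities, the annual tax revenue ($862,722,888/y), the
government administration cost ($8,627,229/y = 1% of revenue), and the
weight-change parameters. Each parameter carries its published 95% interval
or, where none was published, a conventional ±25% band
(`pm25_bounds()`).

Source studies report effects as risks, risk ratios, hazard ratios,
incidence-rate ratios or odds ratios; `multi_year_risk_to_annual()` (the
constant-rate rule `1 − (1 − p_k)^{1/k}`) and `ratio_to_probability()`
(direct scaling for RR, `1 − (1 − p)^r` for HR/IRR, odds-scale inversion
for OR) convert them to annual probabilities. The shipped table already
contains converted annual probabilities; the converters document the
derivation and are available for extending the table.

For probabilistic sensitivity analysis (PSA), each parameter is assigned a
distribution by class — gamma for costs and revenue, beta for probabilities
and utilities, log-normal for ratio measures, normal for the
sign-indefinite tax weight effect — and moment-matched to
(mean, sd) with `sd = (high − low)/3.92`, treating ±25% bands like 95%
intervals since no other rule is available. Two moments determine each
family, so asymmetric printed intervals are honoured in spread but not in
skewness. Three degenerate cases are resolved as point masses: the
normal-weight utility (mean exactly 1, where a beta distribution is
infeasible), the overweight→death probability (printed interval
0.0087–0.0087), and any zero-width interval. A beta sd exceeding the
feasible bound `sqrt(m(1−m))` is clipped. After each PSA draw, any origin
state whose outgoing probabilities sum beyond 1 is renormalised
proportionally so the stay probability remains non-negative.

The tax weight effect is the published −0.56 kg/y (95% CI −1.93, 0.77).
The calorie chain that motivates it — 3.08 g/day less added sugar × 4
kcal/g = 12.32 kcal/day, and `calories_to_weight_rate(12.32)` ≈ 0.58 kg/y
under the 3,500 kcal/lb static rule — does not reproduce −0.56 exactly with
standard constants; the simulation therefore takes −0.56 as the
authoritative input and the converters serve as provenance documentation.

## The synthetic cohort

No survey microdata ship with the package. Instead, baseline weight and
height are drawn from a log-normal × normal joint distribution coupled by a
Gaussian copula, calibrated to the published survey moments of Californian
adults in 2015: mean weight 77.67 kg, SD 19.96 kg, obesity prevalence
28.2%. The log-normal weight parameters are the exact analytic solution
(`sd_log = sqrt(log(1 + (19.96/77.67)²))`,
`mean_log = log(77.67) − sd_log²/2`); height moments are not published, so
they are fixed at mean 1.68 m, SD 0.10 m — ordinary adult anthropometry —
and the copula correlation is the free parameter adjusted by a
deterministic one-dimensional root search (fixed internal draws, 10⁵
evaluations per step) until simulated obesity prevalence matches 28.2%
within 0.5 percentage points. The search settles near `corr ≈ 0.64`.

All individuals start free of diabetes, CVD and ESRD: disease is accrued
only through simulated incident transitions, because the study design
counts new cases over the horizon and no baseline disease prevalence is
specified. Age and sex are not simulated — the transition probabilities are
population-averaged — so the generator reproduces the marginal weight
distribution and its link to height, but none of the age structure,
secular trends, or differential tax response that real survey data would
carry. Passing calibration therefore validates the weight distribution
machinery, not demographic realism.

## Economics

The health-care perspective counts direct medical costs only. The
government perspective adds the administration cost and subtracts the tax
revenue, both discounted at the same 3% as all other flows and both
entering only the tax arm:
`Δcost_gov = Δcost_hc + admin − revenue` (an accounting identity tested in
the suite). The ICER is `Δcost / ΔQALY`; an intervention that saves costs
and gains QALYs is flagged dominant. The cost-effectiveness acceptability
curve (CEAC) reports, per willingness-to-pay λ, the fraction of PSA
iterations with positive net monetary benefit `λ·ΔQALY − Δcost`.

Both arms are always simulated with **common random numbers**: the natural
weight gains and transition uniforms are drawn once per seed, so the arms
differ only through the tax weight effect. With a zero effect the two arm
traces are bit-identical, and incremental estimates have far lower
Monte-Carlo variance than independent arms would give.

The administration cost is drawn as its own ±25% gamma parameter rather
than recomputed as 1% of the drawn revenue; at the point values the two
definitions coincide.

## Problem sizes and the PSA profile

The base case runs 20,000 individuals for 20 cycles (well under a second).
The PSA's default *desk profile* is 200 iterations × 2,000 individuals with
the target population held fixed (the rescale factor adjusts to
29,247,121 / n); the full published profile, 1,000 × 20,000, is available
by argument (`run_psa(..., n_iterations = 1000, n_individuals = 20000)`)
and runs in minutes. The cohort is regenerated from the same seed every
iteration, so the PSA propagates parameter uncertainty only, not population
sampling variation. Parameters are drawn independently; no correlation
structure between them is published.

At a willingness-to-pay of $100,000/QALY the probability the tax is
cost-effective is driven almost entirely by the sign of the weight-effect
draw: with effect ~ N(−0.56, 0.689²), the mass below zero is ≈ 79%, which
is what the CEAC reports at that threshold.

## Consistency of the published inputs, and known limitations

The package reproduces the published calibration moments, the acceptability
probability, and the incremental ("cases prevented") contrasts. It does
*not* reproduce the published 20-year *level* counts of events, and the
reason is arithmetic, not stochastic: the published annual transition
probabilities compound over 20 years to totals well above the published
counts. Even a cohort held at the lowest-risk state (normal weight,
diabetes probability 0.0069/y, death 0.0090/y, no weight gain) accrues a
20-year incident-diabetes total of about
`20000 × 0.0069 × (1 − (1 − 0.0159)^20)/0.0159 ≈ 2,380` persons ≈ 3.5
million rescaled — already above the upper bound of the published interval
for the status-quo count — and the actual cohort, which is mostly
overweight or obese and gains weight every year, accrues more. The same
compounding shortfall propagates to deaths, to total health-care costs, and
(through person-years lost to death) to total QALYs. The package reports
what the stated inputs imply; no hidden rescaling of probabilities is
applied to force agreement.

Related smaller points:

* Published total tax revenue over 20 years is internally inconsistent with
  the published annual revenue (20 × $862.72M ≈ $17.3bn undiscounted,
  ≈ $13.2bn discounted). The package reports its own discounted annuity
  and makes no attempt to match the published total.
* Under coherent revenue accounting the government-perspective increments
  are dominated by the medical-cost term, so the tax is government
  cost-saving roughly as often as the weight-effect draw is negative
  (~80%), and the government ICER is negative in ~98–99% of iterations —
  not essentially always, as it would be if the revenue term dominated.
* "Ever overweight"/"ever obese" case counts include individuals already in
  the category at baseline; only one reading of "cases" is possible for the
  disease states (incident transitions), but for the weight categories this
  is a documented choice.
* Recurrent same-type events (poststroke→stroke, post-MI→MI) are not
  modelled: no probabilities are published for them. Stroke→MI and
  MI→stroke are modelled and restart the receiving tunnel.
* No demographic turnover (aging-in, migration), no direct
  (non-weight-mediated) effect of SSB intake on disease, and no
  societal-perspective indirect costs.
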