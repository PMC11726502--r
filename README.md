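# ssbcea

Individual-level state-transition microsimulation for the
cost-effectiveness analysis of a 1-cent-per-ounce sugar-sweetened beverage
(SSB) excise tax among Californian adults.

The package is aimed at health-economics and policy modellers: it provides
a tested, reusable implementation of a two-arm (soda tax vs. status quo)
Markov microsimulation with annual cycles over a 20-year horizon, driven
entirely by a structured table of published inputs plus a synthetic
baseline population.

## The model in brief

Each of *n* = 20,000 simulated adults occupies one of ten health states:
normal weight, overweight, obesity (assigned from BMI = weight/height²,
overweight 25 ≤ BMI < 30, obesity BMI ≥ 30), diabetes, stroke, poststroke,
myocardial infarction (MI), post-MI, end-stage renal disease (ESRD), and
absorbing death. Stroke and MI are one-cycle tunnel states with acute
costs/utilities, feeding chronic post-event states. Each annual cycle
applies, in order, a natural weight gain U(0.45, 0.91) kg/y plus the tax
arm's weight effect (−0.56 kg/y), BMI reclassification, one sampled
transition from the current state's annual transition probabilities, and
tunnel promotion. Discounted (3%/y) costs (2022 USD) and EQ-5D-weighted
QALYs accrue per state-year; model counts are rescaled by
29,247,121 / 20,000 = 1,462.36 to the Californian adult population.

Cost-effectiveness is summarised from two perspectives with the
incremental cost-effectiveness ratio ICER = ΔC/ΔE and net monetary benefit
λ·ΔE − ΔC at willingness-to-pay λ = $100,000/QALY: health care (direct
medical costs) and government (medical costs + administration cost − tax
revenue, $862,722,888/y). Parameter uncertainty is propagated by
probabilistic sensitivity analysis (PSA): gamma (costs), beta
(probabilities, utilities), log-normal (ratio measures) and normal (weight
effect) distributions moment-matched to each parameter's interval with
sd = (high − low)/3.92, summarised as cost-effectiveness acceptability
curves (CEACs). Both arms always share common random numbers.

Baseline weight/height come from a synthetic cohort (log-normal × normal,
Gaussian copula) calibrated to the 2015 survey moments: mean weight
77.67 kg, SD 19.96 kg, obesity prevalence 28.2%.

See `vignette("soda-tax-microsimulation")` for the full model description,
design choices, and a discussion of where the published inputs are and are
not internally consistent.

## Worked example

```r
library(ssbcea)
run <- run_base_case(seed = 1)
print(run)
```

```
Base-case run: n=20000, 20 cycles, seed 1

Incident events (millions, population scale):
        item soda_tax_millions status_quo_millions prevented_millions
1 overweight            11.817              17.563             5.7456
2    obesity             9.384              16.074             6.6903
3   diabetes             4.222               4.576             0.3539
4     stroke             1.771               1.867             0.0965
5         mi             2.056               2.112             0.0556
6       esrd             0.307               0.329             0.0219
7      death             7.053               7.182             0.1287

Cost-effectiveness summary (population scale) 
  status_quo cost $2239.30 bn, QALYs 0.3529 bn
  soda_tax   cost $1997.34 bn, QALYs 0.3603 bn
  tax revenue (disc.) $13.22 bn; admin cost $0.132 bn
  delta QALY 7.412e+06; delta cost HC $-2.42e+11; delta cost gov $-2.551e+11
  ICER (health care) -32644; ICER (government) -34409 $/QALY
```

Reading this: over 20 years the tax arm accrues ~0.35 million fewer
incident diabetes cases and ~0.13 million fewer deaths than the status
quo; it gains ~7.4 million QALYs and saves ~$242bn in direct medical costs
at population scale, so the tax *dominates* (negative ICER: cheaper and
more effective) from both perspectives. The `prevented` column is the
status-quo count minus the tax-arm count under common random numbers.

The PSA and its acceptability curve:

```r
inp <- load_parameters()
psa <- run_psa(inp$params, inp$config, calibrate_population(n = 2000),
               n_iterations = 200, n_individuals = 2000, seed = 1)
ceac(psa, wtp_grid = 1e5, perspective = "healthcare")
#>     wtp probability
#> 1 1e+05        0.78
```

i.e. at $100,000/QALY the tax is cost-effective in ~78–80% of parameter
draws — essentially the probability that the drawn weight effect is
negative. A command-line wrapper with `simulate` / `psa` / `validate` /
`calibrate` subcommands is installed at
`system.file("cli", "ssbcea", package = "ssbcea")`.

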