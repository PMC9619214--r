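# psmcea

Trial-based cost-effectiveness analysis of oncology treatments with a
three-state partitioned-survival cohort model, from digitized
Kaplan-Meier curves all the way to probabilistic sensitivity analysis.

## The problem

Health-technology assessments of new cancer drugs usually have no
patient-level data to work with: the evidence is a published trial's
progression-free-survival (PFS) and overall-survival (OS) Kaplan-Meier
figures, their numbers-at-risk tables, and a handful of printed
summary statistics. The analyst must

1. recover pseudo individual patient data (IPD) from the digitized
   curves,
2. extrapolate beyond trial follow-up with parametric survival models,
3. run a cohort model that accrues costs and quality-adjusted
   life-years (QALYs) over a lifetime horizon, and
4. characterize decision uncertainty.

`psmcea` implements this pipeline as a tested, reusable R package. It
is shaped around a second-line comparison in *EGFR* T790M-mutant
advanced non-small-cell lung cancer — osimertinib versus
platinum-pemetrexed, evaluated from both a United States payer and a
Chinese healthcare-system perspective, in the intention-to-treat (ITT)
population and the CNS-metastases subgroup — but every input is a
configuration file, so any two-arm comparison with PFS/OS endpoints
fits.

## The model

**States.** Progression-free (PFS), progressed (PD), dead. Occupancy
is read directly off the two survival curves (a partitioned-survival
model): at cycle boundary *t*,

```
pfs(t) = S_PFS(t),   dead(t) = 1 − S_OS(t),   pd(t) = max(0, S_OS(t) − S_PFS(t))
```

with a 3-week cycle, half-cycle correction, continuous-time
discounting `(1+r)^−t`, and a lifetime horizon (20 years or cohort
extinction, whichever comes first).

**Curves.** Pseudo-IPD are rebuilt from digitized curve coordinates
plus the numbers-at-risk table (events from the survival-ratio drops,
censorings as the interval residual, spread deterministically).  Four
families — exponential `S(t)=e^(−λt)`, Weibull `S(t)=e^(−λt^γ)`,
log-logistic `S(t)=1/(1+(t/α)^β)`, log-normal — are fitted by maximum
likelihood and ranked by AIC/BIC. A subgroup's intervention curves can
be derived from the comparator's by hazard-ratio adjustment
(`S^HR`, with the literal survival-scale product available as an
alternative mode).

**Economics.** Regimen definitions (flat, per-m², per-kg dosing;
cycle caps such as four-cycle cisplatin), adverse-event burdens with
the >5-percentage-point incidence-difference inclusion rule,
post-progression subsequent-therapy/BSC mixtures, treatment
discontinuation, and one-off EGFR-testing and end-of-life costs.
Decision outputs: incremental cost-effectiveness ratio
`ICER = ΔC/ΔE`, net monetary benefit `NMB = λ·E − C`, drug-price
threshold search (bisection on incremental NMB), one-way sensitivity
(tornado) tables, and seeded Monte-Carlo probabilistic sensitivity
analysis with cost-effectiveness acceptability curves (costs ~ gamma,
probabilities/utilities ~ beta, HR/BSA/weight ~ truncated normal, all
moment-matched).

A synthetic-trial generator (`make_fixture_study()`) emulates the
whole evidence base — simulated arms with medians anchored to the
published trial (PFS 10.1 vs 4.4 months, OS 26.8 vs 22.5 months),
digitized curves, risk tables, and a complete costed configuration —
so the pipeline is testable end to end without any external data.
All unit costs, utilities and adverse-event inputs it emits are
synthetic stand-ins and are labelled as such.

## Worked example

```r
library(psmcea)

fx  <- make_fixture_study("China", "ITT", seed = 1)   # synthetic study bundle
res <- run_pipeline(fx$config)                        # reconstruct -> fit -> model
res$ce
#> <ce_result> osimertinib vs platinum-pemetrexed
#>   osimertinib            cost $      25005   1.926 QALY   2.695 LY
#>   platinum-pemetrexed    cost $      14303   1.393 QALY   2.093 LY
#>   dC = $10702, dQALY = 0.533, ICER = 20073 $/QALY  [tradeoff]
```

The intervention buys 0.533 extra QALYs for $10,702 — an ICER of
$20,073/QALY, under the Chinese willingness-to-pay threshold of
$37,489/QALY, so it would be adopted. The selected comparator PFS
model is the Weibull the curve was generated from:

```r
res$inputs$fits$comparator_pfs[[1]]
#> <survival_fit> weibull(scale=0.110247, shape=1.30216)
#>   logLik = -346.9228  n = 140  AIC = 697.846  BIC = 703.729
```

Uncertainty analysis on the same bundle:

```r
model <- make_model(fx$config)
defs  <- default_parameter_defs(fx$config)
owsa(model, defs, wtp = 37489)                   # tornado table
psa   <- run_psa(model, defs, iterations = 2000, seed = 1)
ceac(psa, c(19003, 37489, 85176))                # acceptability curve
```

A thin command-line wrapper over the same functions ships in
`inst/cli/cea.R` (`make-fixtures`, `fit`, `run-base`, `run-subgroups`,
`owsa`, `psa`, `ceac`, `threshold-price`, `scenario`).

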