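---
title: "Partitioned-survival cost-effectiveness modelling with psmcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned-survival cost-effectiveness modelling with psmcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

`psmcea` evaluates the cost-effectiveness of one cancer treatment
against a comparator when the only survival evidence is a published
trial's Kaplan-Meier figures. This vignette is the package's own
account of the methods: the model and its assumptions, the conventions
behind each tunable parameter, the numerical choices, what the
synthetic-data generator does and does not emulate, and the known
limitations.

## The cohort model

Three health states: progression-free (PFS), progressed disease (PD),
and dead. The model is *partitioned survival*: state occupancy at each
cycle boundary $t_k$ is read directly off the progression-free and
overall survival curves,

$$\mathrm{pfs}_k = S_{PFS}(t_k), \qquad
  \mathrm{dead}_k = 1 - S_{OS}(t_k), \qquad
  \mathrm{pd}_k = \max\{0,\; S_{OS}(t_k) - S_{PFS}(t_k)\}.$$

This is the construction implied by deriving both transition inputs
from the PFS and OS curves of the same trial. A per-cycle Markov
transition mode (`build_trace(..., markov_mode = TRUE)`), which
propagates occupancy with `cycle_transition_prob()`, is provided for
comparison; for non-crossing curves the two constructions are
algebraically identical, and the test suite asserts their agreement.
Where extrapolated curves cross ($S_{PFS} > S_{OS}$, which fitted
parametric tails can produce), PD is clamped at zero, PFS at $S_{OS}$,
and the number of clamped cycles is reported as an attribute rather
than silently discarded.

Key settings, all in `model_settings()`:

* **Cycle length**: 21 days (one 3-weekly administration cycle);
  $21/365.25$ years for discounting.
* **Horizon**: "lifetime", operationalized as the earlier of 20 years
  or overall survival below 0.1% (`survival_floor = 0.001`). At the
  hazards typical of previously treated advanced NSCLC the cohort is
  extinct well before 20 years, so the cap is inert in practice.
* **Discounting**: continuous-time compound, $(1+r)^{-t}$, applied to
  costs and health outcomes alike; 3% (US) and 5% (China) annual rates
  are the locale defaults.
* **Half-cycle correction**: trapezoid form — each cycle's value is
  weighted by the mean of the occupancies at its two boundaries, and
  discounted at the cycle midpoint. This is the most common reading
  of "half-cycle correction", and the on/off difference is bounded by
  one cycle's value (tested).

Times are in **months** everywhere at the interface; years appear only
inside discounting. Value streams passed to `accrue()` are *per cycle
in the state* (a drug cost is naturally a cost per 3-week cycle); the
life-year and QALY wrappers fold the cycle length in years into the
stream. One-off values attach either to model entry (EGFR testing,
expected adverse-event burden; undiscounted, time zero) or to the
death increment of each cycle (end-of-life care; discounted with the
cycle).

## Survival curves: reconstruction, fitting, selection

**Pseudo-IPD reconstruction.** `reconstruct_interval_counts()` takes a
digitized curve (time/survival pairs) plus the numbers-at-risk table
and rebuilds interval event and censoring counts in the Hoyle style:
within each risk-table interval, the events at each digitized drop are
$n \cdot (1 - S_i/S_{i-1})$ with $n$ reduced by the *events* recorded
so far in the interval; censoring is the residual that reconciles the
risk table, $c_j = n_j - n_{j+1} - d_j$. Censoring within an interval
is assumed uniform and is placed at deterministic equal spacing
(`expand_to_ipd()`), a deliberate divergence from implementations that
sample censoring times: it removes every trace of randomness from the
reconstruction, so everything downstream of a digitized curve is
bit-reproducible. Fractional event counts are rounded by
largest-remainder allocation per interval, which keeps the cohort
account exact: initial $n$ = events + censorings + administrative
censorings at the final follow-up time, always. Beyond the last
risk-table entry, drops still become events but censoring is assumed
purely administrative (everyone remaining is censored at the end of
follow-up).

The simpler event equation (censoring not interleaved into the at-risk
count) slightly overstates drops when an interval contains heavy
random censoring; at trial-like censoring levels the product-limit
curve of the reconstructed records stays within 0.02 of the digitized
input in sup-norm (tested at $n \geq 200$, and on every synthetic
fixture).

**Parametric families.** Four candidates, parameterized as is usual in
health-economic survival analysis:

| family | parameters | $S(t)$ | median |
|---|---|---|---|
| exponential | rate $\lambda$ | $e^{-\lambda t}$ | $\ln 2/\lambda$ |
| Weibull | scale $\lambda$, shape $\gamma$ | $e^{-\lambda t^\gamma}$ | $(\ln 2/\lambda)^{1/\gamma}$ |
| log-logistic | scale $\alpha$, shape $\beta$ | $1/(1+(t/\alpha)^\beta)$ | $\alpha$ |
| log-normal | $\mu$, $\sigma$ | $1-\Phi\!\left(\frac{\ln t-\mu}{\sigma}\right)$ | $e^{\mu}$ |

The Weibull scale is the *rate-like* $\lambda$ (not R's
`dweibull` scale $b$; $\lambda = b^{-\gamma}$), and the log-logistic
scale is the median — chosen so that fitted parameters read directly
as clinical quantities.

**Fitting.** `fit_mle()` maximizes the right-censored log-likelihood
$\sum_{\text{events}} \log f(t_i) + \sum_{\text{censored}} \log S(t_i)$.
The exponential rate uses its closed form $d/\sum t_i$ exactly. The
two-parameter families are optimized by Nelder-Mead on log-transformed
positive parameters (the log-normal location stays natural), from
three fixed, data-derived starting points, keeping the best converged
result, with a $10^{-10}$ relative tolerance — fits are therefore
deterministic functions of the data. Parameter recovery is tested at
$n = 1000$: within 5% of truth uncensored and 10% under roughly 20%
random censoring, for every family; the Weibull and log-logistic fits
are also cross-checked against an independent survival-regression
implementation.

**Selection.** `select_distribution()` ranks fits by AIC
($2k - 2\ell$) or BIC ($k\ln n - 2\ell$), ties broken by fewer
parameters, then a fixed family order. AIC is the pipeline's default
criterion (`selection_criterion` in the configuration exposes the
choice). Two statistical facts matter when interpreting selection
behaviour, and the test suite is written around them:

* AIC is not selection-consistent for nested families: with
  exponential truth, a two-parameter extension out-scores it with a
  fixed asymptotic probability (the boundary likelihood-ratio
  phenomenon), so consistency properties are asserted under BIC.
* Log-logistic and log-normal are intrinsically hard to tell apart:
  in log-time the contest is logistic versus normal, and both families
  are closed under power transforms of time, so the discrimination
  rate is invariant to the shape parameter — about 89% at $n = 300$,
  about 99% at $n = 1000$, regardless of implementation.

**Hazard-ratio adjustment.** Subgroups are modelled by deriving the
intervention's curves from the comparator's fitted curves with the
subgroup hazard ratios. Two modes exist. `proportional_hazards`
($S^{HR}$) is the default: it is the standard transform and always a
valid survival function. `rate_multiply` (the literal survival-scale
product $HR \cdot S$, clamped to $[0,1]$) is retained for replication
of analyses that describe multiplying a hazard ratio into a published
survival rate; it is not a valid survival transform when
$HR \cdot S > 1$, which is exactly why it is not the default. The
wording that inspired it is ambiguous between the two readings, so
both are provided and neither is asserted as "the" published
arithmetic. In the CNS-metastases population the comparator OS curve
is the ITT comparator OS curve unchanged, and only the intervention OS
is HR-derived — the published analysis states that assumption
explicitly.

## Economics

`regimen_cycle_cost()` resolves doses (flat mg, per m² of body surface
area, per kg of weight) against locale anthropometrics, counts
administrations (daily drugs administer once per day of the 21-day
cycle; infusional drugs once per cycle unless configured otherwise),
applies cycle caps (four-cycle cisplatin; pemetrexed continues as
maintenance until progression), and adds infusion costs per IV
administration. Treatment discontinuation (7%/10% in the two arms) is
modelled as removal of drug-acquisition cost for that fraction from
the second cycle onward while the patients remain in PFS with all
other costs — the published rates are stated without a mechanism, and
this is the most conservative reading that keeps state occupancy
untouched. Post-progression care is a per-cycle mixture:
`fraction × subsequent-therapy + (1 − fraction) × BSC`, with fractions
0.53/0.81. Adverse events enter if their grade ≥ 3 incidence differs
between arms by strictly more than 5 percentage points; their expected
management cost and QALY decrement
($\sum \text{incidence} \times \text{disutility} \times \text{duration}$)
are applied once at model entry, a common simplification the source
analysis leaves unspecified. Radiotherapy has a unit cost in the
locale block but no stream of its own: the fixture folds it into the
subsequent-therapy cycle cost, since the published cost list names it
without saying where it attaches.

Incremental analysis reports the raw ratio $\Delta C/\Delta E$ in
every quadrant — a costlier, less effective strategy prints a negative
ICER; a cheaper, less effective one prints a positive south-west ICER —
with a `dominance` flag carrying the interpretation, matching how
published base-case tables print negative ICERs without quadrant
relabelling. The net-monetary-benefit rule ($\lambda E - C$) is the
decision engine for scenario analysis, the price-threshold search, and
the acceptability curve; whenever $\Delta E > 0$ it agrees with
"ICER < WTP" (property-tested on random results). The threshold search
is bisection on incremental NMB, valid because total accrued drug cost
is linear in the unit price (also tested); the default price tolerance
of $10^{-5}$ \$/mg keeps the residual NMB at the returned price well
under \$1.

## Sensitivity analysis

Deterministic: `owsa()` re-evaluates the model at each parameter's low
and high bound with everything else at base, and ranks by the ICER
span. Bounds are the parameter's 95% confidence interval where one is
supplied (the configuration's `parameter_ranges` block), otherwise
±25% of base — the convention of the emulated analysis. If the
incremental effect changes sign across a parameter's range the ICER is
meaningless at that bound; the span falls back to incremental NMB and
the row is flagged.

Probabilistic: `run_psa()` draws every parameter independently per
iteration — costs from gamma, probabilities and utilities from beta,
hazard ratios, BSA and weight from normal truncated positive by
redraw — with distributions moment-matched to (base, se) so each
reproduces its mean and standard error exactly
(`moment_match()`; gamma: shape $= m^2/s^2$, scale $= s^2/m$; beta:
$\nu = m(1-m)/s^2 - 1$, $\alpha = m\nu$, $\beta=(1-m)\nu$). Where only
range bounds exist, $se = (\text{high}-\text{low})/(2 \times 1.96)$,
reading the range as a 95% interval; the divisor is configurable
because that reading is a convention, not a published fact. No
correlation structure is imposed (none is specified by the emulated
design). A normal-scale hazard ratio can go non-positive, hence the
truncation; a log-normal option would be the orthodox alternative, and
the normal-with-truncation choice follows the stated distribution
assignment. The default iteration count is 10,000; the shipped fixture
configuration uses 2,000, which keeps the full PSA under half a minute
on one core while leaving Monte-Carlo error on acceptance
probabilities near one percentage point.

The acceptability curve is the fraction of draws with positive
incremental NMB at each threshold — intentionally *not* forced
monotone, and tested against hand-enumerated fractions on tiny
samples.

## The synthetic study generator

`make_fixture_study()` produces everything an end-to-end run needs:
simulated patient-level arms (inverse-transform draws from the true
distributions; censoring = min(administrative cutoff, exponential
random censoring)), a synthetic digitization (product-limit curve
sampled on a fine grid, survival rounded to 3 decimals to mimic
plot-reading precision, exact at-risk counts at the risk-table times),
and a complete YAML configuration.

What it emulates faithfully:

* trial shape — arm sizes 279/140 (ITT) and 93/51 (CNS); true medians
  anchored to the published ones (PFS 10.1 vs 4.4 months, OS 26.8 vs
  22.5 months; CNS PFS 8.5 vs 4.2 months); log-logistic truths for the
  intervention arm and Weibull for the comparator, the families the
  published analysis selected;
* the published drug prices (6.62 and 0.36 \$/mg for the intervention
  drug in the two locales), anthropometrics (BSA 1.79/1.72 m², weight
  70/65 kg), discount rates, WTP thresholds and dosing rules;
* the CNS assumption that the comparator OS curve is the ITT
  comparator curve (the identical digitized object is reused) with the
  intervention OS declared as an HR adjustment (HR 1.19, range equal
  to its printed CI 0.79–1.83).

What it does **not** emulate: every unit cost, utility and
adverse-event input is a synthetic stand-in (the supplementary tables
carrying the real values are not reproduced), flagged as such in the
generated configuration. Digitization error is idealized as grid
sampling plus rounding — no reader bias, no mis-read risk tables.
Event times are grid-quantized by the digitizer; the grid is fine
(0.25/0.5 months) because a coarse grid lumps reconstructed event
times at grid boundaries and visibly biases the fitted shape
parameters even while the KM round trip stays tight. Consequently,
green tests demonstrate that the *machinery* is correct and that the
pipeline recovers known truths under realistic trial geometry — they
do not validate the stand-in economics against the published totals,
and the fixture's ICERs are expected to differ from the published ones
(only their signs and quadrant structure are comparable).

## Numerical choices and degenerate inputs

* Optimizer: Nelder-Mead, `reltol = 1e-10`, max 2000 iterations, three
  fixed starts; non-convergence from all starts is an error carrying
  the optimizer diagnostics, never a silent fallback.
* `cycle_transition_prob()` with an exhausted curve ($S(t)=0$) returns
  1 with a warning (the state mass is already absorbed).
* Occupancy conservation is enforced to $10^{-9}$ in tests; the death
  state is monotone by construction.
* Ties in distribution selection are resolved to 8 decimal places of
  the criterion, then fewer parameters, then the fixed family order —
  fully deterministic.
* Utilities outside $[0,1]$ warn rather than error (an adverse-event
  disutility can legitimately push an effective utility below the
  state utility); negative durations and infeasible beta parameters
  are hard errors raised before any draw.
* All randomness flows from explicit integer seeds; the PSA,
  simulation and pipeline are bit-reproducible for a given seed, and
  the reconstruction contains no randomness at all.

## Known limitations

* No spline or cure extrapolation models, and no time-varying hazard
  ratios; proportional hazards is assumed wherever an HR derives one
  curve from another (the CNS OS detriment HR is applied over the
  whole horizon).
* The reconstruction implements the interval-residual censoring
  account, not the variant that re-estimates within-interval at-risk
  counts; with very heavy within-interval censoring its event counts
  are biased upward.
* PSA draws are independent; correlated parameters (e.g. the two
  utilities) would need a Cholesky layer that is deliberately out of
  scope.
* The model is a cohort model: no individual-level heterogeneity,
  treatment switching, or tunnel states.
* Vial-size rounding is off by default (exact per-mg pricing); a
  hook exists in the regimen layer but real wastage policies are not
  modelled.
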