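---
title: "Methods: the cohort model, the scenario engine, and its numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cohort model, the scenario engine, and its numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

bamsim projects a national population aged 35–100 through ten health states
one calendar year at a time and asks how alternative futures for
hypertension prevalence would change mortality, dementia and disability
burden, and (healthy) life expectancy. This vignette is the package's own
account of the model: its assumptions, the parameters that matter, the
design choices that were genuinely open, and what the shipped synthetic data
can and cannot tell you.

## The state space and its defaults

Eight alive states are spanned by three flags — cardiovascular disease
(CVD), cognitive impairment (CI) and disability (DIS) — with *dementia*
defined operationally as the coexistence of cognitive impairment and
disability, plus two absorbing death states split by cause (CVD vs
non-CVD). `default_state_space()` encodes the transition diagram:

* CVD and cognitive impairment are irreversible once acquired;
* disability can be acquired from any alive state and recovered from only
  while cognitively intact (`DIS → FREE`, `CVD_DIS → CVD`);
* at most one condition is acquired per year, so dementia is entered from
  `CI` (acquiring disability) or `DIS` (acquiring cognitive impairment) and
  never directly from the disease-free state;
* by default the only exits from the dementia states are the death states;
  `allow_cvd_from_dementia = TRUE` re-opens CVD acquisition there.

These defaults are a modelling choice, not a law: the `state_space()`
constructor accepts any flag table and transition set (the test suite, for
instance, runs a three-alive-state space against an individual-level
microsimulation), so a different diagram is a data change, not a code
change.

Within a simulated year the order of operations is: transitions first, then
ageing by one year (survivors at age 100 remain at 100 — a closed top
interval rather than forced death), then the entrant cohort joins at the
youngest modelled age in the disease-free state. Entrants therefore do not
transition in their entry year. Counts are real-valued expected persons;
the cohort engine is deterministic, and all stochasticity lives in the
synthetic generator's observation noise and the uncertainty module.

## Calendar trends in mortality

Observed cause-specific deaths per (5-year age group, sex, cause, year) are
fitted per stratum with a Poisson regression of deaths on calendar year
with a log-exposure offset. Projected rates under a trend-scenario
multiplier `m` are `rate(y) = exp(α + m β (y − y_ref))`; the seven
sensitivity scenarios use equally spaced `m ∈ {0, 1/3, …, 2}` spanning "no
further improvement" to "a doubled decline" with the central projection at
`m = 1`. Only the endpoints of that range are substantively meaningful; the
equal spacing of the intermediate multipliers is our choice and is
configurable.

Projected rates enter the Markov model as multiplicative scaling of the
death-transition probabilities relative to a base year (the end of the
fitting window), with the stay probability absorbing the complement. This
mechanism was chosen because it preserves row-stochasticity and the
relative-risk structure between states; rates pinned to a base year mean
multiplier 1 reproduces the unscaled table exactly. Scaled probabilities
are clipped into [0, 1] (and the row renormalised if the stay probability
would go negative), with every clipping event logged on the run's `meta$log`
— a run that clips is a run whose inputs deserve a second look. The same
multiplier mechanism accepts optional incidence-trend tables.

Age-group-level quantities (mortality multipliers, prevalence, relative
risks) apply uniformly to every single age in their 5-year group.

## Prevalence scenarios and the impact-fraction engine

Observed hypertension prevalence per (5-year age group, sex, survey year)
is fitted by ordinary least squares of log prevalence on year (unweighted:
survey design weights are not modelled). Three futures then share the
observed history and diverge the year after the last observation:

* **baseline** — the fitted log-linear trend, capped into
  `[floor, 1]` with `floor = 1e-4` so downstream attributable fractions
  stay well-defined (capping is logged);
* **constant** — the last observed value, every year;
* **optimistic** — the last observed value times
  `exp(log(r) (y − y_last)/(y_target − y_last))`, reaching reduction
  fraction `r` (default 0.5) at the target year (default 2060). The path
  between the endpoints is not dictated by the scenario definition;
  log-linear interpolation was chosen for consistency with the baseline's
  log-scale trend, and linear interpolation is available via
  `interpolation = "linear"`.

Scenario differences act on transition probabilities through Levin's
population attributable risk fraction and its difference form (the
potential impact fraction for a discrete risk factor):

$$\mathrm{PARF} = \frac{P(RR-1)}{1 + P(RR-1)}, \qquad
\Delta\mathrm{PARF} = \frac{(P - P')(RR-1)}{1 + P(RR-1)},$$

with the baseline scenario's prevalence as \(P\) and the counterfactual's
as \(P'\), so the baseline keeps its original probabilities and
counterfactuals are adjusted relative to it:
\(tp' = tp\,(1 - \Delta\mathrm{PARF})\), the stay probability again
absorbing the change. One uniform rule serves all six affected transition
types — including disability *recovery*, where the stratum relative risk is
below one, so a prevalence decline yields a negative \(\Delta\) and the
recovery probability rises. Relative risks are held constant over calendar
time. Using adjusted relative risks inside Levin's formula is known to be
biased; the package follows the standard practice of accepting that bias
because the object of interest is the *comparison* of scenarios, not the
absolute attributable burden.

## Outcome definitions

All outcome measures are restricted to ages 65+ by default.

* Incident cases are flow sums from states lacking a condition flag into
  states carrying it; a move from `DIS` into `DEM` is a dementia incident
  but not a disability incident, while `CI → DEM` is both (disability is
  newly acquired there).
* Person-years use the mid-year approximation (average of start-of-year and
  start-of-next-year alive counts).
* Cumulative differences run from 2015 with the sign convention "avoided > 0
  = benefit"; the per-100 000 denominator is the *baseline* scenario's
  cumulative person-years 65+ over the same window — the only denominator
  consistent with a cumulative numerator.
* Life expectancy at 65 is period life expectancy from the model-implied
  single-year death probabilities of one calendar year, with a half-cycle
  correction `L(a) = l(a)(1 − q(a)/2)` and an open-ended top interval
  contributing `l(100)/q(100)` (a zero top-age death probability is an
  explicit error). Healthy life expectancy weights `L(a)` by the fraction
  of each age's alive population in healthy states (Sullivan's method).
  *Healthy* excludes exactly CVD, dementia and disability; cognitive
  impairment alone therefore still counts as healthy — a deliberate reading
  of a three-exclusion definition — and `healthy_states` overrides it.
  Both-sex life expectancy pools deaths and populations before forming
  `q(a)`; per-sex values are also emitted.

## Uncertainty propagation

`run_psa()` resamples inputs per iteration — beta for transition
probabilities (mean = point estimate, spread set by an effective sample
size), beta for prevalence observations, lognormal for relative risks,
normal for fitted mortality slopes — reruns all scenarios on the same draw
(common random numbers, so scenario differences are within-draw and their
intervals reflect the scenarios rather than sampling noise), and reports
percentile 2.5/97.5 intervals. These families are standard probabilistic
sensitivity practice where distributions are otherwise unspecified; all
hyperparameters sit in `psa_distributions()`. Independent beta draws leave
the stay probability to absorb the residual (a row pushed past probability
one rejects the draw, which is logged and skipped; more than 1% failures
aborts); `dirichlet_rows = TRUE` instead draws whole rows from a Dirichlet,
guaranteeing row sums by construction. Percentile intervals of a nonlinear
model need not bracket the central run, and the package does not force them
to.

## The synthetic generator: what it does and does not emulate

`generate_all()` produces every input the pipeline needs with the
statistical structure the analysis assumes: a 60-million-person all-age
population whose 35+ share follows a piecewise-linear age density;
condition occupancy rising with age; logistic-in-age incidence and
Gompertz-like death probabilities (so generated incidence and mortality are
age-monotone); hypertension prevalence 2003–17 declining on the log scale
with configurable observation noise; cause-specific mortality 2007–16 with
log-linear decline and optional Poisson noise; attenuating-with-age
relative risks above one for incidence and death types and below one for
recovery; and constant entrant cohorts of 380 000 per sex per year.

The default prevalence decline is set at −0.008/yr on the log scale: a
genuine decline, but deliberately shallower than a halving spread over
2017–60 (−0.0161/yr), because a steeper trend would make the optimistic
scenario indistinguishable from baseline and the three-way comparison
degenerate. Magnitudes are tuned to the order of national burden figures
(hundreds of thousands of deaths 65+ per year) so directional checks run in
a realistic regime — the generator does **not** claim to reproduce any real
calibration, and passing tests on synthetic data demonstrate correctness of
the machinery, not the accuracy of any substantive projection. Survey
sampling design, attrition, interval censoring of panel observations, and
migration at ages above 35 are not emulated; entrants are the only
demographic inflow.

`generate_toy_example()` is the opposite extreme: three age groups, flat
round-number probabilities, noiseless inputs — small enough for hand
arithmetic, and frozen as the golden regression fixture of the test suite.

## Numerical choices and test problem sizes

Row sums are validated to 1e-9; conservation of persons is asserted to
1e-6 relative; impact-fraction and life-table identities to 1e-12.
Zero-delta and zero-multiplier adjustments are exact no-ops by
construction (increment form, not row renormalisation), which is what makes
the null-scenario equivalence checks bitwise. The test suite exercises the
engine-versus-microsimulation oracle on a three-alive-state space (ages
60–70, ten years, ~100 000 simulated persons, three-standard-error bands),
recovers a −0.02 Poisson trend slope over 200 replicates at 10⁵
person-years exposure, and runs the Monte Carlo contracts at 200 iterations
on a reduced miniature — sizes chosen to make the checks sharp while the
whole suite stays comfortably runnable on a laptop.

## Known limitations

Transition-probability estimation from panel data is out of scope: the
probabilities are inputs. No constraint ties projected total mortality to
an external principal projection. Disability from causes other than CVD and
dementia is one aggregate state with averaged transition probabilities.
Single risk factor only — no joint risk-factor distributions, no
time-varying relative risks, no cost or cost-effectiveness layer, and no
decomposition of life-expectancy differences.
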