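---
title: "Model and methods: the S-1 switching cost-effectiveness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: the S-1 switching cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(s1switch)
```

## The decision problem

Hand-foot syndrome (HFS) and cardiovascular toxicity (CVT) are
fluoropyrimidine toxicities that force a treatment decision in metastatic
colorectal cancer: continue capecitabine or i.v. 5-FU at reduced dose,
discontinue first-line chemotherapy until progression, or switch to the
alternative oral fluoropyrimidine S-1 (alone, or combined with oxaliplatin
as SOX or irinotecan as IRIS). `s1switch` models the lifetime costs and
quality-adjusted life years (QALYs) of these strategies for a closed
cohort of patients at the moment the toxicity occurs, and compares them
with incremental cost-effectiveness ratios (ICERs), a dominance frontier
and net-monetary-benefit acceptability curves.

Three bundled scenarios fix the clinical setting by the first-line
treatment on which toxicity occurred: `"capox"` and `"folfox"` (four
strategies each) and `"cap_mono"` (three strategies). Strategies are named
`first line -> second line`, e.g. reduced CAPOX -> irinotecan.

## The cohort model

The engine is a Markov cohort model with a 1-week cycle and five states:
first-line treatment, progression (a transient one-week state), second-line
treatment, progressed without treatment, and death (absorbing). Patients
leaving the progression week split 80% : 20% between starting second-line
treatment and remaining untreated. All second-line treatments are assumed
equally effective; treatment beyond the second line is outside the model.

Transition probabilities are recomputed every week from Weibull survival
distributions fitted to trial data, with time measured in weeks from the
switch: overall survival (OS) Weibull(shape 1.473, scale 79.4) and
time-to-progression (TTP) Weibull(1.560, 53.9). The weekly probability is
the conditional event probability `1 - S(t+1)/S(t)`, evaluated through the
cumulative hazard so it stays defined when `S(t)` underflows. Strategy
effects act as relative risks (RR) multiplying the weekly probability,
clamped at 1: S-1-based first lines carry RR 0.93 on death (and 1.0 on
progression), discontinuation carries RR 1.50 on both, and reduced-dose
continuation carries RR 1.0 (reduced dose is taken as fully effective —
an assumption, not an estimate). Multiplying the probability rather than
the hazard is a deliberate literal reading of how the effect is defined;
at the weekly probabilities involved (below 0.05) the two conventions
differ by less than 2% relative, which a unit test documents.

Several orderings of within-week events are defensible; we evaluate death
first, then progression among survivors. Two consequences recommend this
choice: the cohort's survival curve then reproduces the fitted OS
distribution *exactly* (a property the test suite asserts at 1e-6), and
the combined weekly exit probability `p_death + (1 - p_death) * p_prog`
can never exceed 1. The same OS process, on the common time origin,
drives death from every alive state: no separate post-progression
survival model is introduced, and second-line treatment continues until
death (no stopping rule is imposed). There is no half-cycle correction —
with weekly cycles its effect would be far below every other source of
uncertainty.

The horizon is 780 weeks (~15 years), chosen so that under the default
parameters (and across the probabilistic draws) less than 0.1% of the
cohort remains alive at the end; the engine tracks cohort fractions, with
the nominal 1000-patient cohort used only for presentation.

## Costs, utilities, discounting

Regimens are costed per cycle — 3 weeks for oral and short-infusion
regimens, 2 weeks for i.v.-5FU regimens — and converted to weekly costs.
The bundled components (EUR per cycle, 2024 Dutch prices, body surface
area 1.95 m2) are S-1 mono 398, S-1 combination 331, reduced capecitabine
180, oxaliplatin 556, 5FU+leucovorin 208, irinotecan mono 677, irinotecan
combination 348, short i.v. administration 335, long (48h+)
administration 1288. These yield weekly costs of €60 (reduced
capecitabine), €133 (S-1), €337 (irinotecan), €338 (IRIS), €357 (CAPOX),
€407 (SOX) and €1026 (FOLFOX). One bundled source prints CAPOX at €320
per week, which is inconsistent with its own components and with the €357
that appears elsewhere; the component arithmetic is adopted, as it is the
only internally consistent choice. Irinotecan monotherapy is assigned the
3-week (350 mg/m2) schedule — the only cycle length consistent with €337
per week.

Adverse events (recurrent HFS and CVT, plus diarrhoea and anorexia) are
assumed to occur immediately at the switch and last 2 weeks. Recurrence
probabilities after the switch are 0.55 (HFS) and 0.40 (CVT) when
continuing capecitabine/5FU versus 0.05 and 0.04 on S-1. Only HFS (€50)
and CVT (€200) carry management costs — the per-arm expected
adverse-event cost (0.55·50 + 0.40·200 = 107.5 vs 10.5) reproduces the
published per-strategy cells, confirming that reading. Both probabilities
apply to the whole cohort simultaneously; the expected cost enters once at
week 0, undiscounted. Diarrhoea and anorexia probabilities are not
published and default to 0; if set, they contribute disutility only. The
calibration table states the adverse-event disutility lasts 3 weeks while
the methods text says 2; the package defaults to 2 (`ae.duration_weeks`
in the config), and switching to 3 moves QALYs by well under 0.01.

Utilities: 0.83 on first-line treatment, minus 0.15 on second-line
treatment, minus 0.10 when progressed without treatment, 0 at death. The
transient progression week carries the 0.10 decrement (the source assigns
it no utility; patients in that week are progressed and not yet treated).
Adverse-event disutilities (0.15 per event) are probability-weighted,
additive and floored at utility 0 during the event weeks.

Costs are discounted at 3% per year and utilities at 1.5% per year with
`weeks_per_year = 365.25/7`; reported medians convert weeks to months by
×7/30.44.

## Probabilistic sensitivity analysis

Each PSA run draws one parameter set shared by all strategies of a
scenario (paired comparisons — the incremental quantities would otherwise
be far noisier):

* every cost component from a gamma distribution with shape `sqrt(c)` and
  rate `1/sqrt(c)`, so the mean is exactly the point estimate `c` and the
  variance `c^1.5` (the garbled two-number gamma notation in the
  calibration table is ignored in favour of this stated rule);
* the S-1 OS relative risk from lognormal(-0.0726, 0.058), median 0.93,
  applied to S-1-based strategies only — the discontinuation RR has no
  published distribution and stays fixed at 1.50;
* the first-line utility from N(0.83, 0.01), truncated to [0, 1];
* the OS and TTP (shape, scale) pairs from bivariate normals with the
  fitted means, standard errors, and bootstrap shape-scale correlations
  0.555 (OS) and -0.255 (TTP), redrawn while non-positive. Truncation
  versus redrawing is immaterial at these standard errors (both events
  have negligible probability); redrawing was chosen for simplicity.

Each run's random stream is seeded from a master seed through a per-run
seed table, so results are reproducible and independent of execution
order. The default 1000 runs matches the published analysis; tables of
results are means over runs, and ICERs are computed on those means (not
as means of per-run ratios).

## Comparing strategies

The frontier sorts strategies by mean cost, removes strictly dominated
ones, then iteratively removes extended- (weakly-) dominated strategies
until the stepwise ICERs increase monotonically. Strategies whose cost
and QALY differences are both negligible (|dQALY| < 0.005 and
|dcost| < €100) are flagged *equivalent* — this operationalises the
published treatment of SOX -> irinotecan versus SOX -> IRIS, whose €41
cost difference is far inside model noise; both are retained and
reported. ICERs are also reported against the common discontinuation
reference, since the published tables use both presentations.

Acceptability curves evaluate, on a willingness-to-pay (WTP) grid from €0
to €100 000 in €1000 steps (the published range; the step is not stated),
the fraction of runs in which each strategy has the highest net monetary
benefit `WTP × QALYs - cost`. Exact ties break toward the cheaper
strategy (a conservative payer convention), implemented as a vanishing
cost penalty that cannot perturb genuine differences. The *turning point*
is the lowest WTP at which the most probable strategy is no longer the
cheapest one.

Sensitivity variants rerun the PSA with the discontinuation RR at 1.2 or
1.8, or with OS parameters refitted on patients surviving a 9-week
landmark (HFS tends to appear after about three full cycles). For the
landmark variant the refitted means replace the OS means while the
published standard errors and correlation are retained, as no refitted
uncertainty is available.

## The synthetic trial module

No patient-level calibration data are deposited, so `simulate_ipd()`
generates a synthetic stand-in at trial scale: by default 160 patients,
uniform accrual over 104 weeks, administrative censoring at a 156-week
study end (about 20% censoring on OS) — a typical phase-III-like
structure chosen once as realistic, since the source trial's exact size
and censoring are not printed. OS and TTP are drawn independently and TTP
is then capped at OS (progression after death is unobservable); the
induced dependence is the only one modelled, as no joint model is
published. Whether real TTP was death-censored or treated as a competing
risk is unknown; synthetic TTP is censored at death or study end.

`fit_parametric()` fits exponential and Weibull models by right-censored
maximum likelihood (via `flexsurv`, with the shape/scale parameterisation
used throughout) and compares them by AIC; `refit_conditional()` fits the
9-week-survivor model with a left-truncated (delayed-entry) likelihood,
keeping the original time origin rather than resetting the clock —
matching "estimated on patients who survived 9 weeks" without changing
what the scale parameter means. `bootstrap_shape_scale_corr()` reproduces
the bootstrap that generated the shape-scale correlations.

The emulation reproduces the *structure* of trial data, not the trial
itself: passing parameter-recovery and coverage tests shows the
estimation machinery is sound, not that the synthetic cohort matches the
real one. Consequently the trial-derived published numbers (Kaplan-Meier
medians of 14.8 and 8.9 months, bootstrap correlations 0.555/-0.255) are
treated as inputs, never as quantities this package should reproduce.

## Numerical and reporting choices

* Weekly probabilities through `-expm1(-dH)`: stable under survival
  underflow at extreme parameters.
* The cohort recursion is evaluated in closed vectorised form (alive mass
  and progression-free mass are cumulative products; the post-progression
  states accumulate a cumulative sum thinned by death), so mass
  conservation holds to machine precision.
* Reported "median TTP" is ambiguous in the source (its printed values
  exceed both the trial median and the marginal Weibull median, with no
  stated definition); the package reports the median progression week
  among progressors and treats the printed column as unreproducible.
* Written outcome tables round to whole euros, 2-decimal QALYs and
  1-decimal medians, matching the published precision; raw-precision
  tables are written alongside.
* Test and verification problem sizes are chosen to keep the full suite
  in the low minutes while leaving Monte-Carlo error well inside the
  asserted bands: 1000-run PSAs for table-level checks, 5000 draws for
  distribution checks, 300 replicate fits for coverage.

## Known limitations

* No treatment beyond second line, no bevacizumab (its costs and effects
  are assumed to cancel), and no microsimulation — cohort fractions only.
* The discontinuation relative risk (1.50) is expert opinion; the
  sensitivity variants at 1.2 and 1.8 bracket it, and the key ICER is
  strongly sensitive to it.
* Costs are Dutch 2024 prices; no indexing or currency conversion is
  provided.
* The synthetic trial module cannot validate the fitted survival
  parameters against real data, only the fitting machinery.
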