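---
title: "Model and methods: cost-utility analysis of kidney allocation strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: cost-utility analysis of kidney allocation strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kidneyalloc)
```

## The decision problem

Deceased-donor kidneys are scarce; allocation rules decide who gets which
kidney, and thereby how many graft-years and quality-adjusted life years
(QALYs) the donor pool yields and what the dialysis program costs. This
package evaluates four *longevity-matching* allocation options against
current practice for a cohort of waitlisted end-stage kidney disease
patients, from the healthcare payer's perspective, in 2018 Australian
dollars.

## Cohort model

The model is a four-state Markov cohort process in one-year cycles:
**waitlisted** (on dialysis), **transplanted**, **post-graft-failure
dialysis**, and **death**. The entire cohort (default 1000 patients) starts
waitlisted. Waitlisted patients are transplanted or die; transplanted
patients suffer graft failure, die, or continue with a functioning graft;
after graft failure patients remain on dialysis until death — re-listing
and re-transplantation are not modelled. The default horizon is 20 cycles.

### Time-dependent transitions and tunnel states

Three transitions are time-dependent and follow Weibull
proportional-hazards laws with an age covariate, with cumulative hazard

$$H(t) = \lambda\, e^{\beta \cdot age}\, t^{\gamma},$$

fitted by `fit_weibull_ph()` (maximum likelihood via
`flexsurv::flexsurvreg(dist = "weibullPH")`, whose rate/shape
parameterization and multiplicative covariate effect on the rate match this
form exactly). The per-cycle transition probability is the conditional
probability of the event in cycle $t$ given survival to $t-1$:

$$tp(t) = 1 - \exp\!\big(H(t-1) - H(t)\big),$$

the canonical decision-model conversion: compounded over cycles it
reproduces $1 - e^{-H(T)}$ exactly (a tested invariant). The age covariate
enters uncentered as $e^{\beta\cdot age}$, evaluated at age 50 throughout;
the cohort does not age within the model.

The transplant-to-graft-failure and transplant-to-death hazards are
functions of time since *transplant*, not model time, because they are
fitted on survival from transplant. The transplant state is therefore
expanded into one tunnel state per year since transplant. The
waitlist-to-transplant hazard, by contrast, runs on model time, since the
whole cohort is listed at time zero. Waitlist mortality (0.0184/year) and
post-graft-failure mortality (0.1091/year) are fixed annual probabilities,
obtained from cumulative incidences via the rate conversion
$r = -\ln(1-p)/T$, $p_{annual} = 1 - e^{-r}$
(`cumulative_incidence_to_annual_probability()`), and shared by all arms.

Competing exits from a state are independently computed annual
probabilities. If their sum ever exceeds 1 the model rescales them
proportionally and warns; with the shipped parameters this never occurs
(one-year exit probabilities stay far below 1), so the choice of
competing-risk adjustment is immaterial here.

### Payoffs, discounting, and accounting conventions

Per cycle, waitlist and post-graft-failure occupancy accrue the annual
dialysis cost (81,689.34 AUD) and the dialysis utility (0.70); transplant
tunnels accrue the transplant utility (0.82); death accrues nothing.

Published cohort models rarely state their within-cycle accounting in full,
so the conventions are explicit flags on `model_config()`, with defaults
chosen — once, during model validation against the published base-case
league table — as the combination that reproduces all five arms' totals
within 1.5%:

* **Payoff timing.** Payoffs accrue on end-of-cycle occupancy. A
  half-cycle correction (trapezoid of start- and end-of-cycle occupancy) is
  available but off by default.
* **Discounting.** Costs and QALYs are discounted at 5%/year; the first
  cycle is undiscounted, i.e. cycle $t$ carries $(1.05)^{-(t-1)}$.
  `discount_from_first_cycle = TRUE` switches to $(1.05)^{-t}$.
* **Transplant-year-one cost.** The transplant episode cost (99,968 AUD) is
  applied once, on first-year tunnel occupancy, *in addition to* the annual
  maintenance cost (13,916 AUD), i.e. a patient's first graft year costs
  113,884 AUD and later years 13,916. `maintenance_in_first_year = FALSE`
  restores the episode-only convention. Full cost is applied regardless of
  within-cycle transplant timing (no proration).

Each flagged alternative changes totals by 1–5%; none changes any
qualitative conclusion (dominance labels, orderings) with the shipped
parameters.

### A parameter sign correction

The shipped current-practice graft-failure age coefficient is $-0.020$.
The source parameter table prints $+0.020$ for this single cell while every
other option's graft-failure coefficient is negative. The positive sign is
internally inconsistent: $e^{0.020\times 50} = e$ triples the current-arm
graft-failure hazard and pushes its 20-year totals more than 25% away from
the published league table, whereas the negated value places all five arms
within 1.5% of it. We treat the printed sign as a transcription error; the
YAML parameter file records the choice.

## Economic comparison

`compute_icer()` reports $\Delta$cost, $\Delta$QALY, and
ICER $= \Delta C / \Delta E$ with the usual cost-effectiveness-plane
classification: cheaper and more effective is *dominant*, costlier and less
effective *dominated*; in the off-diagonal quadrants the signed ICER is
reported. ICERs are computed on unrounded totals; printed league-table
values are truncated toward zero to whole AUD, matching common reporting.
Net monetary benefit is $NMB = WTP \times QALY - Cost$; options are ranked
by incremental NMB versus current practice at WTP 28,000 AUD/QALY, with
42,000 and 67,000 as scenario thresholds.

## Probabilistic sensitivity analysis

`run_psa()` re-evaluates every arm per iteration (default 20,000) under
parameters drawn from the distributions in `psa_distributions()`:

* Weibull $\lambda, \gamma$: Normal(mean, SEM), truncated at a floor of
  $10^{-8}$ to preserve validity — truncation, not rejection, guarantees
  termination, and with the shipped SEMs a truncated draw is vanishingly
  rare; $\beta$: Normal, untruncated.
* Fixed probabilities: Beta with shapes solved by method of moments from
  (mean, SEM); infeasible moments ($\mathrm{sem}^2 \ge m(1-m)$) are an
  error. The deterministic base case uses the point values; the Beta draw
  applies only in the PSA.
* Costs: Uniform over ±15% of the point value (cost data are not expected
  to be skewed). Utilities: Uniform over their 95% CI bounds (transplant
  0.74–0.90, dialysis 0.62–0.78).

Parameters are sampled independently (no published covariance matrix).
Parameters shared across arms — fixed probabilities, costs, utilities — are
drawn once per iteration and used by every arm, so within-iteration
increments isolate the allocation-specific transition parameters. Draws are
taken parameter by parameter in a fixed documented order, making runs
reproducible by seed and invariant to iteration count ordering. Degenerate
distributions (all SEMs zero, zero-width ranges) reproduce the base case
bit-for-bit, a tested invariant; the engine propagates all iterations
simultaneously through one code path shared with the deterministic run.

### Probability of error

The **probability of error** of an option is the fraction of iterations in
which it does not return the highest NMB. Two comparator sets are
plausible: against current practice alone (*pairwise*) or against the full
option set (*all*). Both are implemented; **pairwise is the default**. The
choice was settled empirically during validation: the pairwise rule
reproduces all three originally reported error probabilities within 0.05,
while the full-set rule yields values 0.3–0.4 higher for every option, and
the original description of the quantity ("the proportion of iterations in
which an allocation method returns the highest NMB, compared to the current
method") reads most naturally as pairwise. Ties count as non-highest under
both rules.

## Synthetic registry generator

`generate_registry()` stands in for the restricted registry linkage the
analysis design assumes. It emulates, per patient: age at listing
(truncated normal, mean 50, SD 13, range 18–80); listing uniform over an
11-year study window with administrative censoring at the window's end (the
only censoring mechanism exposed — loss to follow-up is not modelled, as
the real linkage's censoring pattern is unpublished); waitlist transplant
times from the Weibull law by cumulative-hazard inversion; waitlist death
as a geometric-in-years process (integer event years, matching the
annual-probability treatment of these transitions); post-transplant
graft-failure and death as latent Weibull times with the earliest kept
(standard latent-failure-time construction; ties — probability zero in
continuous time, but possible against the integer-year death process — are
broken in favour of death). A companion `generate_dialysis_cohort()`
emulates the second linked dataset, incident dialysis patients with
post-graft-failure survival.

EPTS and KDRI are generated as monotone noisy functions of recipient and
donor age: $score = \exp(a + b\cdot age + \varepsilon)$,
$\varepsilon \sim N(0, 0.12^2)$, because no joint distribution of scores
and ages is published. The default links are calibrated so that the
allocation-rule thresholds are mutually consistent: recipient ages 41 and
60 map to EPTS 1.033 and 2.4806, donor ages 32 and 58 to KDRI 0.9148 and
1.7208 — the quintile/quartile score cutoffs land at the same people as
the corresponding age cutoffs, producing realistic overlap between strata.
Donor age is mildly assortative with recipient age (slope 0.3) to mimic
incidental matching under current practice.

`apply_allocation_option()` mirrors the design's subsetting exactly:
records violating an option's pairing rule are *excluded*, not reassigned;
untransplanted records always pass through; the operation is idempotent.

What the generator does **not** emulate: the real marginal KDRI/EPTS
distributions, organ-offer logistics, waitlist suspensions, re-listing, or
secular trends. Tests passing on synthetic data therefore validate the
*code* — fitting, subsetting, conversions, engine — not the clinical
realism of any parameter value.

## Verification strategy and problem sizes

The test suite validates each stage against an independent route:

* closed forms: telescoping cycle probabilities, geometric waitlist decay,
  hand-computed payoff arithmetic, the $T=1$ identity of the
  incidence-to-probability conversion;
* an individual-level microsimulation of 200,000 patients walking the same
  transition process, agreeing with cohort occupancies within 3 binomial
  standard errors at every cycle;
* parameter recovery: Weibull fits on synthetic registries of 10,000
  patients recover the generating $(\lambda, \gamma, \beta)$ within 3 SEM,
  and Kaplan–Meier curves from 20,000 generated records stay within 0.02
  sup-distance of the specified survival function;
* reproduction of the published base-case league table (totals within 2%,
  all dominance labels exact) and uncertainty analysis (error
  probabilities within 0.06, NMB ordering preserved at all three
  thresholds) at the full 20,000-iteration PSA size.

## Known limitations

* **Incremental magnitudes.** This reimplementation reproduces the
  published *totals* (within 1.5%), all dominance labels, the NMB ordering
  and the error probabilities, but its incremental costs versus current
  practice are 2–5 M AUD more favourable to the transplant-intensive
  options than originally reported, and the mean incremental NMBs
  correspondingly larger. Increments are differences of two ~400 M totals:
  they are dominated by within-cycle accounting details of the original
  implementation (built in commercial decision-modelling software) that
  were never published. A systematic
  search over payoff/discount conventions, time bases and
  cycle-probability constructions found no variant that matches all
  published increments simultaneously while remaining consistent with the
  published totals. The acceptance report therefore states the NMB means
  as computed; direction, ordering and decision conclusions agree.
* Age is fixed at 50; no within-cohort age distribution or ageing.
* No re-transplantation, organ-transport costs, or waitlist suspension.
* PSA ignores parameter covariance and model-structure uncertainty.
* The scale of the standard errors of $\lambda$ (natural vs log) is
  unstated in the source table; sampling is on the natural scale.
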