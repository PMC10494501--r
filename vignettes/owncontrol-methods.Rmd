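---
title: "Self-controlled effectiveness analysis of osteoporosis medications: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-controlled effectiveness analysis of osteoporosis medications: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design

`owncontrol` implements an own-control (self-controlled) cohort analysis
of fracture incidence after initiation of an osteoporosis medication in
longitudinal claims data. Each woman serves as her own reference: the
fracture rate in later risk windows is compared, within a treatment
cohort, to the rate in the first three months after initiation, when the
pharmacological benefit of antiresorptive and anabolic agents is assumed
to be minimal. This removes confounding by every time-invariant
characteristic — bone density, fracture history, frailty — measured or
not. The immediate post-initiation period, rather than the
pre-treatment period, is the reference because these drugs are often
started right after a fracture; a pre-treatment reference would inflate
the baseline through regression to the mean and masquerade as a
treatment effect.

The pipeline covers five treatment cohorts (denosumab, zoledronic acid,
teriparatide, oral bisphosphonates as one class, raloxifene) built from
three claims tables: persons, drug dispensings, hospital stays.

## Treatment episodes

Dispensings are chained into continuous-coverage episodes. All intervals
are half-open `[start, end)` in integer days; dates become calendar
strings only at I/O. The conventions, where the underlying design
language is calendar words, are fixed once in days: 3 months = 91 days,
6 months = 183, 1 year = 365, 2 years = 730, 3 years = 1095.

* **New-user index.** The index date for a drug is the earliest
  dispensing in the inclusion window (2014-01-01 to 2016-12-31 by
  default) with no dispensing of the same drug — same class for the
  three oral bisphosphonates — in the prior 365 days. A delivery that
  fails the washout does not index, but a later delivery may once it
  re-satisfies it.
* **Coverage chaining.** Each delivery covers `units ×
  coverage_days_per_unit` days starting at the later of its date and the
  previous coverage end (stockpiled supply carries forward; the standard
  persistence convention). The episode persists while the next delivery
  arrives within a 30-day grace period after the current coverage end.
* **Discontinuation.** No refill within the grace period ends the
  episode; the discontinuation date is the last day covered by the last
  delivery, i.e. `end_day − 1` under the half-open convention. This
  removes the off-by-one ambiguity that calendar phrasing leaves open.
* **Censoring events.** Death and end of data truncate episodes with
  their own reasons; initiation of a different study drug before the
  episode end re-labels it a switch, ending the day before the new
  drug's first delivery.

Coverage days per unit are configuration, not a claim about any national
database: oral bisphosphonates and raloxifene 30 d per monthly pack,
denosumab 182 d, zoledronic acid 365 d, teriparatide 28 d.

## Eligibility and hierarchical assignment

Women qualify with an index at age ≥ 55, a 3-year look-back, a 2-year
follow-up window in the data, at least 183 days of treatment, no
cancer/Paget code in the prior year, and no second study drug dispensed
on the index date. Two deliberate readings:

* The follow-up requirement is measured from index to the end of the
  person's data; dying within the two years does not disqualify — death
  is a censoring event, not an exclusion.
* Exclusion reasons are not mutually exclusive; the flow table counts an
  excluded woman under every reason that applies.

Eligible women holding episodes of several drugs are assigned to exactly
one cohort by market-entry recency (denosumab, zoledronic acid,
teriparatide, oral bisphosphonates, raloxifene); the chosen episode's
index date becomes the woman's index date.

## Fracture events

Hospitalized fragility fractures are identified from diagnosis codes in
principal, related or associated position (and procedure codes in any
position) via a longest-prefix code map. The default map (ICD-10-style
S72 hip, S220/S320/T08 vertebral, S52 wrist/forearm, etc.) is an
editable stand-in, clearly not a validated national code list; real
analyses must substitute an audited mapping. Events are dated at
admission — the standard claims convention, since onset is not recorded.

A same-site recurrence counts as an independent event only if it occurs
at least 90 days (inclusive: a gap of exactly 90 qualifies; the boundary
is unit-tested) after the previous independent event of that site, with
no fracture of another site strictly between the two dates. Flagged
duplicates are retained for audit but never counted. Events feed four
overlapping site groups: hip; vertebral; wrist/forearm; non-hip/
nonvertebral (wrist/forearm, humerus, clavicle, ribs, pelvis, leg).

## Person-time and analysis modes

Windows relative to index: baseline `[0, 91)`, then `[91, 365)`,
`[91, 548)`, `[91, 730)`. Person-time in a window is its intersection
with the at-risk interval `[index, censor)`; events are counted in the
same intersection. Baseline events never censor follow-up — the estimand
is the incidence of independent events, not time to first event. Three
censoring modes:

* **as-treated** — the episode end (earliest of discontinuation, switch,
  death, end of data);
* **intent-to-treat** — death or the study end (2018-12-31 by default),
  ignoring treatment;
* **virtual exposure** — the episode end plus a drug-specific carry-over
  (365 days for bisphosphonates including zoledronic acid, 30 days
  otherwise), capped at death/end of data.

For discontinuers a post-discontinuation window runs from the end of
coverage to the first dispensing of any study drug, death, or end of
data. Rates are per 1000 person-years with person-years = days/365.25.
The post hoc analysis of early oral-bisphosphonate discontinuers applies
the same as-treated accumulation to women excluded for under-183-day
episodes, over baseline and `[91, 183)`.

## Rate and rate-ratio inference

Rates carry exact Poisson (Garwood) intervals. The IRR of a risk window
versus baseline uses the exact conditional method: given the total
event count, the window's count is binomial with success probability
`p = PY₁·IRR / (PY₁·IRR + PY₂)`; the Clopper–Pearson interval for `p`
inverts to an interval for the IRR. Zero counts yield one-sided finite
bounds (0 or ∞); both counts zero flags the cell undefined without
stopping the run. A log-normal approximation
(`log IRR ± 1.96·√(1/x₁ + 1/x₂)`) is available as an option, and the
method used is recorded in every output row. No multiple-testing
adjustment is applied. IRR tables carry log-transformed columns for
forest plots; undefined rows are dropped from plot data with a count.

The exact conditional interval is deliberately conservative at small
counts; at the moderate counts used in the checks below its empirical
coverage sits near the upper half of the 93–97% band.

## The synthetic generator

`simulate_claims()` generates the three claims tables plus ground truth.
Each woman receives one drug, an index date uniform in the inclusion
window, an age from a truncated normal (≥ 55) matching her cohort's
profile, a 3-year-plus look-back and observation until the study end.
Her fracture process is piecewise-constant Poisson per anatomical site:
baseline hazard on `[index, index+91)`, baseline × on-treatment
multiplier until the true end of exposure, baseline ×
post-discontinuation multiplier afterwards. Hazards are keyed by site,
not by the overlapping analysis groups, so the planted group-level IRRs
stay well defined; default magnitudes mirror treated osteoporotic
populations (vertebral ≈ 9 per 1000 PY at baseline, non-hip/nonvertebral
≈ 22). Every true event produces one hospital stay admitted on the event
date, with a site code in principal position (a configurable fraction in
associated position exercises the code-position logic).

Refills fall at `index + k·coverage + jitter`, with non-negative jitter
truncated at 20 days by default — within the 30-day grace, so planned
durations are realised exactly; configuring jitter beyond the grace
makes the generator produce genuine early discontinuations. Planned
durations are log-normal with per-drug medians (≈ 12–17 months),
truncated at 183 days: the generator emulates the *included* population.
For the same reason the death hazard (10 per 1000 PY) starts at day 183
post-index, so that with all exclusion fractions zero every generated
woman passes eligibility — a property the tests rely on. Inter-refill
gap distributions are stipulated, not estimated from any real database.
Planted exclusions (cancer codes, under-55 ages, a second drug on the
index date) are drawn independently per woman.

What the generator does **not** emulate: comorbidity-correlated hazards
(hazards depend only on period and drug), seasonal or calendar effects,
coding noise, switching behaviour, and real national coding practice.
Passing tests therefore demonstrate that the pipeline recovers known
parameters under the design's own assumptions, not that those
assumptions hold in any particular claims database.

## Numerical choices and degenerate inputs

* Dates are integer days; all window arithmetic is exact.
* Empty stays tables run end to end, producing zero rates and undefined
  IRRs rather than errors.
* Zero person-time cells are flagged, never divided by.
* Cohort assignment breaks the (impossible, ranks are unique) tie
  deterministically via `with_ties = FALSE` after sorting by rank.
* Reruns with the same configuration and seed are byte-identical; the
  generator draws all randomness under a single seed.

## Problem sizes used in the checks

The packaged checks use sizes chosen to make Monte-Carlo error small
relative to the tolerances while keeping a desk-scale run: brute-force
day-by-day oracle comparisons on 1,000 simulated women; hazard
conservation at 50,000 women within 3 Monte-Carlo standard errors;
planted-parameter recovery (on-treatment vertebral IRR 0.5,
post-discontinuation IRR 2.0, with a raised vertebral baseline of 35 per
1000 PY so that baseline counts are moderate) at 20,000 women; and
interval coverage of a unit IRR over 200 replicates of 2,000 women.

## Known limitations

* The default fracture code map and comorbidity weight table are
  synthetic stand-ins; the comorbidity score is a configurable
  weighted-flag score, **not** the modified Charlson index.
* The hierarchical assignment and eligibility are evaluated per episode;
  a woman excluded on one drug may qualify on another, which is the
  intended reading but differs from a strictly person-level flow.
* Calendar-word criteria are fixed in days; studies using true calendar
  months will differ by a few days at boundaries.
* The pipeline reports post-discontinuation rate increases; it does not
  adjudicate their cause.
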