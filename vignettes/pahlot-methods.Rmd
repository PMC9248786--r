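---
title: "Methods: treatment lines, utilization, and costs from PAH claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: treatment lines, utilization, and costs from PAH claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahlot)
```

## The problem

Pulmonary arterial hypertension (PAH) is treated with drugs from three
pathway families, grouped here into six medication classes: endothelin
receptor antagonists (ERA), phosphodiesterase-5 inhibitors (PDE5I), soluble
guanylate cyclase stimulators (SGC), and oral, inhaled, and parenteral
prostacyclin / IP-receptor agonists, which are kept as three distinct
classes because their clinical roles differ. Administrative claims record
the fills and administrations of these drugs together with enrollment
spans, diagnoses, procedures, and paid amounts. `pahlot` turns such claims
into the standard descriptive outputs of a treatment-pattern study: a
cohort selected by sequential inclusion/exclusion criteria, each member's
ordered lines of therapy with the reason each line ended, mutually
exclusive regimen labels per line, and all-cause and PAH-related
utilization and cost summaries expressed per patient per month (PPPM).

Because real claims databases are proprietary, the package also ships a
seeded synthetic-claims generator that plants a complete answer key
(index dates, line sequences, period costs), so the whole pipeline is
testable end to end with zero-tolerance comparisons.

## Data model and conventions

* **Days, not dates.** All dates are integer day offsets from a
  configurable epoch (default 2015-10-01, the start of the
  member-identification window). ISO dates are accepted on input and
  converted once.
* **Half-open intervals** `[start, end)` everywhere (enrollment spans,
  coverage intervals, analysis periods). This removes off-by-one ambiguity
  from gap arithmetic.
* **Months** are a fixed `365.25 / 12 = 30.4375` days. The studies this
  mirrors report months but compute from daily claims; a fixed divisor
  makes every month-denominated number reproducible.
* Multi-valued code fields (`dx_codes`, `proc_codes`) are `';'`-separated
  strings so the on-disk format stays plain RFC-4180 CSV. Diagnosis
  position 1 is primary, but PAH-relatedness uses *any* position.
* An inpatient stay is one claim at its admission day; counting logic
  counts stays, not bed-days.

## Cohort selection

Eight sequential criteria, with counts after each step forming the
attrition report: (1) presence in the database; (2) at least one PAH
medication claim — pharmacy fill or HCPCS-coded medical administration —
in the identification window, the earliest becoming the **index date**;
(3) age ≥ 18 at index (year precision, since claims extracts carry birth
year); (4) at least one inpatient claim, or outpatient/ER claims on two
distinct days, with a PH/PAH diagnosis in the 183-day baseline window
ending *on* the index day; (5) a right heart catheterization claim in the
same window; (6) no PAH medication claim between the start of continuous
enrollment and the day before index (treatment-naive); (7) at least 183
days of continuous enrollment before index; (8) at least 30 days after.
Follow-up runs from index to the earlier of disenrollment and the day
after study end.

Two windows deliberately differ by one day: the diagnosis/RHC windows
include the index day ("before and including"), while the
treatment-naive scan stops at index − 1. "6 months" is implemented as a
fixed 183 days. ER claims count on the outpatient side of the two-claim
diagnosis rule, the usual claims convention for ER visits without
admission. Enrollment continuity is strict by default (`bridge_gap = 0`),
configurable for sensitivity analyses that bridge administrative gaps.

## The line-of-therapy algorithm

Coverage comes from days'-supply run-out: a fill covers
`[fill_day, fill_day + days_supply)`; a medical administration covers a
configurable 30 days. Per class, intervals are unioned — an early refill
does not stack supply (a `stack_supply` mode exists for sensitivity
analysis).

A line starting at day *s* is defined by its **formation window**: its
class set is every class with a claim in `[s, s + 30]` (boundary
inclusive by default; both conventions are implemented and tested). Two or
more classes make the line combination therapy. Scanning forward:

* **Modification** — a claim of a class outside the line's set, occurring
  without an intervening interruption, ends the line on that day and
  starts the next line there. This covers both sequential combination
  (the old classes continue) and switches (they stop being filled). A
  new-class claim arriving within the grace period after run-out is still
  a modification, by direct reading of "without treatment interruption".
* **Interruption** — when all-class coverage runs out and more than
  `gap_days = 60` uncovered days pass before any PAH medication claim.
  The line ends on the run-out day; the next claim — including a restart
  of the same drug — opens a new line. A gap of exactly 60 days is
  tolerated: the published footnotes describe the operational rule as "a
  maximum fixed gap of 60 days", and that reading is used (threshold
  configurable).
* **Censoring** — follow-up ends first. A terminal gap no longer than the
  grace period is censored, not interrupted, because the interruption
  cannot be observed within follow-up; this avoids immortal-time
  artifacts at the end of the record.

The formation window is re-anchored at every line start; the published
definition is stated only for line 1, but without it later sequential
combinations could not be classified at all. Drug-level changes within a
class (sildenafil → tadalafil) never break a line; drugs are recorded for
the per-line medication tallies. All lines are segmented; lines beyond
the fourth are flagged unreported but still count toward per-member line
totals.

Regimens are mutually exclusive: one class → monotherapy of that class;
exactly {ERA, PDE5I} → the named ERA + PDE5i combination; any other
multi-class set → "other combination".

The engine is event-driven (it walks claims, maintaining the running
all-class run-out). Its oracle in the test suite is a literal day-stepping
simulator that advances one calendar day at a time; the two agree exactly
on thousands of random histories, including deliberately awkward timings.

## HCRU and costs

Every rate and cost is PPPM with the **pooled denominator**: the sum of
events (or inflation-adjusted costs) over members in a period divided by
the summed patient-months of that period — not the mean of member-level
ratios. Periods are the fixed 183-day baseline, the variable post-index
period, and one period per reported line; claims falling between lines
(during gaps) belong to the post-index period but to no line.

A claim's cost is plan-paid + member-paid + coordination-of-benefits,
multiplied by the calendar-year multiplier of an editable inflation table
(defaults approximate the US medical-care CPI, normalized to 2020 = 1; no
network retrieval). PAH-related scope keeps medical claims with a PAH
diagnosis in any position (or a mapped HCPCS drug administration) and
pharmacy fills of mapped PAH drugs. The baseline PAH pharmacy cell is
emitted as structurally missing rather than zero: the cohort is
treatment-naive before index by construction, and the published table
leaves that cell blank.

Exact identities, enforced by tests on every run: total PPPM = medical +
pharmacy PPPM; PPPM × pooled months = raw adjusted sum; PAH-related ≤
all-cause in every cell.

## The synthetic generator

Generation is **trajectory-first**: the answer is sampled, then claims
are emitted to realize it exactly.

**What is planted exactly.** Attrition fates (each planted failure passes
every earlier step and fails exactly its step), first-line regimen mix,
line-2/3/4 regimen mixes (subject to modification feasibility — a
modification line must contain a class new to the member), and the
restart share among first-line interrupters are allocated by largest
remainder rather than independent draws. This removes needless Monte
Carlo variance from quantities the study states as simple proportions; it
is a variance-reduction choice, not an inference claim.

**What is drawn stochastically.** Follow-up is truncated-lognormal
(moment-matched to mean 18.5 / SD 15.4 months, truncated to [1.05, 63];
draws use the inverse-CDF so they are exactly reproducible). At each line
start the member faces a competing-risk candidate event — interruption
with per-line probability `q`, else modification — at a time drawn from a
two-component mixture: an "early event" uniform on [1.05, `fast_hi`]
months with weight `w`, else a truncated lognormal tail. The event is
observed only if it fits inside residual follow-up (interruptions
additionally need their 61st uncovered day to be observable); otherwise
the line is censored at end of follow-up. This is what makes censored
first lines systematically shorter than overall follow-up, as in real
cohorts, where members who "remain on therapy" are disproportionately
those observed briefly.

**Calibration.** The per-line parameters `(q, w, meanlog, sdlog,
fast_hi)` were fitted once by simulation so that the *emergent* fate
shares and months-in-line match the configured targets (line 1: 39.7% /
29.7% / 30.6% and 7.8 months, achieved to within 0.1 percentage points
and 0.03 months at calibration scale), and then frozen into
`generator_config()`. Changing the targets requires re-running that
one-off calibration; the procedure (grid over the mixture shape, bisection
on the lognormal location against the persistence share, fixed-point
update of `q` against the interruption share) is deliberately simple.

**Exact engine recovery.** Fills are placed so that no tie-break rule is
ever exercised by default: within-line refills are contiguous; the last
fill's supply is trimmed so the all-class run-out lands exactly on the
planted line end; modification and censoring leave at most a 15-day
uncovered tail (well under the 60-day grace); restart gaps are 75–180
days (well over it); formation-window offsets stay ≤ 27 days (inside the
window under either boundary convention); planted ages avoid the 18-year
boundary. Members generated this way are flagged `unambiguous`, and for
them the pipeline must — and in the tests does — reproduce the answer key
with zero errors. Tie-break behaviour itself is tested separately with
hand-built histories and the day-stepping oracle.

**Costs.** Each member-period gets a budget of PPPM target × months × a
lognormal member factor (σ = 0.5); the budget is split over the period's
claims by setting weights (inpatient ≫ ER > outpatient) or medication
class weights with lognormal claim noise (σ = 0.6), deflated to nominal
dollars by the inflation table, and rounded to cents. The answer key
records the realized adjusted sums, so cost recovery is exact while
pooled PPPM is unbiased for the configured targets. Degenerate settings
(zero variance, zero targets) collapse to exact equalities and are
tested.

**Attrition profile at desk scale.** The source database's literal step-2
retention (thousands out of tens of millions) is meaningless at a few
thousand simulated members. The default profile keeps the ordering of the
later steps but compresses the pass rates (≈ 0.94–0.985 per step, cohort
fraction ≈ 0.75), so planted failures of every step appear and the cohort
stays large enough for stochastic recovery checks. A literal profile can
be configured.

**What the generator does not emulate.** Small printed cells ("≤10") in
the published per-line medication tables were imputed to make block
totals exact; the within-class drug choice is independent of regimen
(no joint table exists to calibrate against); utilization counts are
Poisson, so percent-with-≥1 figures emerge from the rates rather than
being planted (real claims are overdispersed); months-in-line for lines
2–4 run shorter than the published 7.4/6.8/6.4 because entrants' residual
follow-up binds at this scale; per-line cost columns inherit the overall
post-index cost level rather than the published line-specific gradients;
and follow-up averages ≈ 17 months after study-end truncation rather than
18.5. Passing tests therefore demonstrate correctness of the algorithms
and calibration of the planted quantities — not that the generator is a
statistical twin of any real claims population.

## Problem sizes and determinism

The test suite exercises: exhaustive enumeration of all 63 class subsets;
~1,200 random engine-vs-oracle histories; planted-truth recovery at 200
and 500 members; calibrated recovery and the PPPM identities at 2,000
members; and byte-identical reruns of the full pipeline at 120 members.
`scripts/acceptance.R` regenerates a 2,000-member population per seed and
recomputes every headline quantity from scratch in about a minute. All
randomness flows from a single integer seed through R's RNG; truncated
distributions are sampled by inverse CDF, so results are identical across
platforms with the same RNG kind.

## Known limitations

* Age uses year precision (birth year only), so ages can be off by up to
  one year relative to exact birth dates.
* The diagnosis-criterion treatment of ER claims and the inclusive
  formation-window boundary are conventions; both are configurable and
  the boundary is tested in both modes.
* The 365-day cap on gap evaluation mentioned in some published footnotes
  is implemented (`gap_eval_cap_days`) but off by default, since the
  companion text describes a variable post-index period; enabling it is a
  sensitivity analysis.
* Suppression is presentation-layer only. Outputs written by
  `apply_suppression()` redact small cells, but the underlying CSVs of
  true counts are also written; a disclosure-controlled release would
  ship only the redacted set.
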