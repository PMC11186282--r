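---
title: "Methods: antimicrobial-consumption surveillance metrics for intensive care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antimicrobial-consumption surveillance metrics for intensive care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amcsurv)
```

## The problem

Antimicrobial stewardship programmes need reliable, high-resolution measures
of antimicrobial consumption (AMC) in intensive care, where drug use is
intense and case-mix strongly confounds crude comparisons. When every signed
drug dose carries a timestamp, an ATC code, a substance amount and a route,
consumption can be measured automatically from the medication-administration
record instead of from pharmacy invoices. `amcsurv` implements that
computation: from raw admission and administration records to stratified
consumption metrics, exposure categories, exposure-linked mortality and
consumption trends.

## Metrics

Three complementary metrics are computed over *calendar days* (wall-clock
dates, not 24-hour windows from admission):

* **DOT** (days of therapy): one unit per distinct antimicrobial agent per
  calendar day per admission, regardless of dose. A patient on two agents
  the same day accrues 2 DOT.
* **LOT** (length of therapy): the number of calendar days with at least one
  antimicrobial, irrespective of how many agents. DOT ≥ LOT always, and
  DOT/LOT measures the frequency of simultaneous multi-drug exposure.
* **Administered DDD**: the administered substance mass divided by the WHO
  defined daily dose for that substance and route. Drugs without a defined
  DDD (for example sulfamethoxazole/trimethoprim) or dosed in units
  incommensurable with the DDD unit (colistin in mass units against an
  MU-denominated DDD) still count for DOT and LOT; they are excluded from
  DDD sums *by omission*, and the excluded share of DOT is reported so the
  omission is visible.

All metrics are normalised per 1000 patient-days, where a patient-day is 24
hours of care: the denominator is the sum of stay hours divided by 24, never
a rounded day count. Rates with a zero denominator are reported as absent,
never as zero, as is the DOT/LOT ratio when LOT is zero.

The surveilled set is defined by registry membership: the bundled
`atc_registry.tsv` covers the systemic antibacterials (J01, plus
rifampicin) and antifungals (J02) in routine ICU use, with route-specific
DDDs where the WHO index distinguishes routes. Class labels sit at the ATC
4th level with explicit overrides (2nd- vs 3rd-generation cephalosporins are
separated). The registry is a curated subset, not the full WHO index, and is
user-replaceable; combination products carry one ATC code and therefore
count as one agent.

## Episodes and attribution

The analysis unit for length of stay, exposure and mortality is the
*intensive-care episode*: a readmission beginning strictly less than 48
hours after the previous discharge continues the episode; a gap of exactly
48 hours starts a new one (the boundary is configurable, and the strict
reading is documented rather than inferred). Member admissions are never
fused, so each dose attributes to the unit that administered it; the gap
between discharge and readmission contributes neither LOS nor patient-days,
because only time under ICU care should divide consumption. The gap is
measured discharge-to-admission. Episode outcomes propagate by rule: ICU
death if any member admission ended in ICU death, 30-day status from the
last admission, severity (SAPS 3 and its estimated mortality rate, EMR)
from the first.

Doses signed outside the admission interval are a fact of EMR life (signing
delays); they are clamped to the interval boundary and logged, with a
1-hour tolerance separating routine delays from grossly out-of-interval
registrations in the log. Dropping them instead would silently lose
consumption. Orphan administrations, inverted intervals and malformed rows
are rejected with a machine-readable issue log; every rejected row appears
exactly once, so `rows in = records out + rejects` holds for every reader.
Timestamps are interpreted as local clinical wall-clock time with no DST
adjustment, because day attribution is calendar-day based.

## Exposure and mortality

Antimicrobial exposure per episode counts distinct *drug classes* (not
agents) over the whole episode, bucketed none / one / two / three / more
than three. Stays are split at LOS > 48 h (strictly more than 2.0
patient-days), longer stays carrying a higher risk of healthcare-associated
infection. Exposure is evaluated at episode scope because the 48-hour merge
exists precisely to treat a readmission as the same care event.

For each exposure level the package reports the mean SAPS 3 EMR with a
normal-approximation 95% confidence interval (mean ± 1.96 SE) and the
observed ICU and 30-day mortality. Episodes missing EMR or vital status are
omitted and counted, never imputed. No risk adjustment or causal modelling
is attempted: the output is a stratified description.

## Trends

The daily series assigns each calendar date its DOT (summed across units)
and its fractional occupied bed-days (each admission contributes its
overlap with the date in hours/24). The trend of DOT per 1000 patient-days
is fitted with an *unpenalised* cubic regression spline — 8 interior knots
at empirical date quantiles, least squares, Gaussian response on the rate
scale (the scale on which the trend is displayed) — with a pointwise 95%
band from the fit covariance. Penalised alternatives exist; the unpenalised
regression spline is the simplest member of that family with the stated
knot count, and both knot count and placement are configurable. Because
cubic polynomials are nested in the basis, a cubic (or constant) generating
curve is recovered up to noise; this is what the trend tests assert.

## Reporting conventions

Every printed rate is `rate_per_1000_pd()` of the same stratum's totals —
tables are views over one per-admission metric table, so stratified totals
conserve grand totals across any complete partition by construction, and
there is no re-derivation drift. Rounding happens only at the rendering
edge and is half-up (matching printed surveillance tables, where 1261.31
prints as 1261): rates per 1000 patient-days to integers, percentages to
one decimal in the population table and to integers in exposure tables.
Clinic-level rates carry a 95% percentile bootstrap interval (1000
admission resamples by default, seeded; the statistic is the ratio of
resampled DOT to resampled patient-days, so both numerator and denominator
variation enter). Rendering is deterministic given the seed, and every
output file carries a provenance header with the tool version and a
configuration hash.

The dispensed-vs-administered DDD comparison divides pharmacy shelf supply
by patient-days *including* under-18 admissions when those are supplied,
since the shelf also serves them; the minors count is echoed in the table.
The mechanism is a declared choice — source data for such comparisons
rarely document one — and the divergence flag (dispensed/administered DDD
ratio above 1.5 by default) marks drugs whose shelf consumption is not
captured by signed doses, the classic example being perioperative
cloxacillin prophylaxis drawn from an ICU shelf.

## The synthetic generator

`generate_synthetic()` exists so the whole pipeline is testable without
patient data. Its defaults, set by `calibrate_generator()` from
`reference_targets()`, emulate a published four-year two-level Scandinavian
ICU cohort of 5608 admissions: care-level mix (2744 secondary / 2864
tertiary), referring-clinic mix with per-clinic log-normal LOS matched on
median and IQR, 41.3% female, ages with median 65 (IQR ≈ 48–75), SAPS 3
severity per care level with EMR = plogis(−8.3 + 0.115·SAPS 3) (reproducing
the published median EMR of 0.08/0.14 at the two care levels' median
scores), 30-day death drawn Bernoulli(EMR), ICU death as a 0.45 subset,
readmission gaps log-normal around 36 h (straddling the 48-h merge window),
inter-unit transfers, and two pandemic case-mix waves (spring 2020, spring
2021) that damp prescribing among flagged medical admissions.

Three calibration details are themselves modelling decisions:

* Per-clinic log-normals matched on median/IQR do not reproduce the
  published care-level *overall* LOS median (real stays are not
  log-normal), so a common per-care-level log-shift is solved numerically
  to put the mixture median on target (1.0 d secondary, 1.8 d tertiary).
* LOS is truncated to [2 h, 60 d]: the unbounded log-normal tail implied
  by wide clinic IQRs would otherwise produce multi-month stays that
  dominate the patient-day denominator.
* Prescribing intensity per care level is calibrated against the published
  DOT rates (1177/1261 per 1000 patient-days) by two fixed-point pilot
  iterations on an internal cohort, since course starts are near-linear in
  the hazard scale. Achieved rates on fresh seeds land within roughly ±10%,
  which is the cohort-level sampling variability at these sizes.

Dose timestamps are drawn at nursing rounds (06/12/18/24 h ± 45 min),
deliberately exercising the calendar-day boundary; one drug is dosed
four-times daily so midnight-crossing jitter occurs. One surveilled drug
has no DDD and one is dosed in mass units against an MU-denominated DDD, so
the omission paths are exercised end to end. A small fraction of doses
(0.6%) lose their ATC linkage, mirroring the per-mille missing-linkage
share such systems report.

Crucially, the generator enumerates ground truth (per-admission and
per-episode DOT, LOT, DDD, exposure) in plain base R at generation time,
*not* via the metrics module; `truth.json` is therefore an independent
oracle, and the test suite requires exact agreement.

What the generator does **not** emulate: microbiology and infection
diagnoses, escalation/de-escalation timing, within-day dosing
individualisation, seasonal admission patterns, or any dependence of death
on exposure beyond what severity induces. Passing tests therefore
demonstrate the *computation* is right under realistic structure, not that
the package's outputs on real data would match any particular hospital.

## Problem sizes and numerical choices

The test suite and the acceptance script run the pipeline on cohorts of
roughly 60–5000 patients: conservation is checked over 20 random seeds at
n = 60, oracle equivalence on ≥ 1000 episodes, mortality calibration on
≥ 5000 episodes (each level's observed mortality within 3 binomial standard
errors of its mean EMR), and episode construction against a brute-force
pairwise-gap union-find oracle including admissions chains of up to 50 with
gaps placed on both sides of — and exactly at — the 48-hour boundary.
DDD comparisons use a 1e-9 tolerance (floating-point summation); DOT, LOT,
exposure and the episode partition must match exactly. Bootstrap intervals
are percentile-based; on a five-admission toy they are checked against the
exhaustively enumerated resample distribution.

## Known limitations

* The registry is a curated ~40-substance subset of the WHO ATC/DDD index;
  sites with broader formularies must extend the TSV.
* The 48-h merge assumes clean patient identifiers; no probabilistic
  linkage is attempted.
* Mortality denominators can be read per admission or per episode;
  `population_table()` reports per admission and `mortality_summary()` per
  episode, and the two differ when readmissions merge.
* The trend model is descriptive; it is not an interrupted-time-series
  analysis and supports no inference about change points.
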