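# amcsurv

Automated surveillance metrics for antimicrobial consumption (AMC) in
intensive care.

Antimicrobial stewardship in the ICU needs consumption measures with enough
resolution to see changes in use over time and across patient groups,
without relying on pharmacy invoices that also count drugs never given to a
patient. When the electronic medication record signs every dose with a
timestamp, an ATC code, a substance amount and a route, consumption can be
computed directly from administrations. `amcsurv` is that computation as a
portable R package: it turns raw admission and medication-administration
CSVs into the standard surveillance outputs used by infection-prevention
teams.

## What it computes

For a patient receiving agents on calendar days, with `PD` fractional
patient-days (stay hours / 24):

* **DOT** — days of therapy: `#{(admission, calendar day, distinct agent)}`;
  a day on two agents counts twice.
* **LOT** — length of therapy: `#{(admission, calendar day with ≥1 agent)}`.
* **Administered DDD** — `Σ administered mass / WHO defined daily dose`
  per substance and route (WHO ATC/DDD index values; bundled curated
  registry).
* Rates are normalised per 1000 patient-days: `rate = total / PD × 1000`;
  derived ratios include DOT/LOT (simultaneous-exposure frequency), LOT per
  admission and LOT per antimicrobial-use admission.
* Admissions re-admitted within 48 h merge into one **episode**; episodes
  are classified by drug-class exposure (none/1/2/3/>3 classes), split at
  LOS > 48 h, and linked to SAPS 3 predicted vs observed mortality.
* Daily DOT-rate trends are smoothed with a cubic regression spline
  (8 interior knots) with a pointwise 95% band.

A calibrated synthetic-data generator (`generate_synthetic()`) emulates a
two-level ICU cohort and writes independently enumerated ground truth, so
the whole pipeline is testable with no patient data.

## Worked example

```r
library(amcsurv)

# the rate arithmetic used throughout: 14466 DOT over 11469 patient-days
rate_per_1000_pd(14466, 11469)
#> [1] 1261.313        # printed as 1261 DOT per 1000 patient-days

# generate a synthetic cohort and run the full report
config <- calibrate_generator(n_patients = 500, seed = 7)
sim    <- generate_synthetic(config, dir = "amc_demo")

registry <- load_atc_registry()
adm   <- read_admissions("amc_demo/admissions.csv")
doses <- read_administrations("amc_demo/administrations.csv", registry)
report <- build_report(adm$records, doses$records, registry,
                       dispensing = read_dispensing("amc_demo/dispensing.csv")$records,
                       n_boot = 200, seed = 7)
report
#> AMC surveillance report
#>   535 admissions, 514 episodes, 1860 patient-days
#>   secondary: 456 DOT (924 per 1000 patient-days), DOT/LOT 1.32
#>   tertiary: 1810 DOT (1324 per 1000 patient-days), DOT/LOT 1.68
```

The per-care-level table behind that summary (`report$metrics_by_level`):

```
  care_level  dot  lot patient_days dot_rate dot_lot_ratio lot_per_amu_admission
1  secondary  456  346        493.5      924          1.32                  2.77
2   tertiary 1810 1077       1366.7     1324          1.68                  5.15
```

`report$exposure_mortality$summary` links exposure with outcomes — at this
cohort size the severity gradient across exposure levels is already
visible (mean predicted EMR rising from 0.15 with no exposure to 0.21 with
more than three drug classes, 30-day mortality from 11% to ~18–24%):

```
            level   n mean_emr emr_ci_low emr_ci_high icu_mortality mortality_30d
1            none 192    0.153      0.127       0.179         0.036         0.109
2             one 135    0.161      0.125       0.196         0.044         0.141
3             two  71    0.173      0.129       0.218         0.099         0.183
4           three  49    0.190      0.131       0.250         0.122         0.245
5 more_than_three  67    0.215      0.160       0.270         0.060         0.179
```

`render_report(report, "amc_out")` writes the full CSV bundle (population
table, clinic tables, class consumption, clinic consumption with bootstrap
CIs, metric comparison against dispensing data, exposure and mortality
tables, data-quality summary), each with a provenance header and
deterministic rounding.

A thin command-line wrapper is installed at
`system.file("cli", "amcsurv.R", package = "amcsurv")` with subcommands
`validate | metrics | report | trend | simulate`.

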