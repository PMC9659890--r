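# apclaims

Drug-utilization and adherence analysis of antipsychotics in
reimbursement-claims data.

## What it is for

Claims databases such as the French national health-insurance sample (EGB,
a 1/97th random sample of the reimbursement database) record every pharmacy
dispensing — date, molecule, units, strength, prescriber specialty — but
neither the prescribed dose nor whether the drug was taken. `apclaims` is
for pharmacoepidemiologists who want to characterize chronic antipsychotic
use from such data. It implements, as tested and reusable functions:

* **cohort selection** — patients aged ≥ 18 dispensed the same
  antipsychotic in three consecutive calendar months (one per calendar
  month), continuously insured over the 12-month lookback, with ≥ 12
  months of follow-up; follow-up ends at the earliest of death, a > 183-day
  antipsychotic-free gap (loss to follow-up), or the study end;
* **primary antipsychotic (PAP) assignment** — among qualifying molecules,
  the one dispensed over the longest first-to-last span wins; cyamemazine
  and levomepromazine (anxiety/aggressiveness indications in France) only
  qualify when nothing else does; span ties go to the first-dispensed
  molecule, residual ties are broken deterministically and flagged for
  adjudication;
* **adherence** — the percentage of days without treatment (%DwT) over the
  12 months (360 days) from the index dispensing, assuming each dispensing
  covers 30 days. With dispensings \(d_1 < d_2 < \dots\),

  %DwT = 100/360 × ( Σᵢ max(0, dᵢ − dᵢ₋₁ − 30) + max(0, 360 − (d_last + 30 − d₁)) )

  Early refills bank no supply; the theoretical maximum, reached with the
  minimum three dispensings and nothing after, is exactly 75%;
* **dispensed daily dose** — mg/day dispensed between one month
  post-inclusion and the last in-window dispensing (an empirical quantity,
  distinct from the WHO defined daily dose);
* **co-dispensing counts, prescriber specialty, comorbidity lookback**, and
  the descriptive report: per-molecule distribution with generation
  classes, SGAP/FGAP ratio, long-acting share, co-treatment bins, and
  n/mean/SD/median/quartile summaries per molecule.

Because claims data cannot be redistributed, the package includes a seeded
**synthetic-claims generator** (`simulate_population()`) with controllable
refill delays, polypharmacy, coverage gaps, death and dropout, plus a fixed
edge-case population (`simulate_edge_cases()`). See the methods vignette
(`vignettes/antipsychotic-utilization.Rmd`) for the model, conventions, and
what the generator does and does not emulate.

## Worked example

```r
library(apclaims)

claims <- simulate_population(simulation_config(n_patients = 500, seed = 42))
claims
#> <ap_claims>
#>   500 patients, 21312 dispensings, 448 hospital diagnoses
#>   189 ALD records, 520 coverage spells

res <- run_ap_pipeline(claims)
table(res$exclusions$reason)
#>   coverage_gap      no_triple short_followup       under_18
#>             19             22             56              8

str(res$report$summary)
#> List of 11
#>  $ n_cohort           : int 395
#>  $ fgap_count         : int 152
#>  $ sgap_count         : int 182
#>  $ sgap_fgap_ratio    : num 1.2
#>  $ fgap_percent       : num 45.5
#>  $ sgap_percent       : num 54.5
#>  $ long_acting_count  : int 5
#>  $ long_acting_percent: num 1.3
#>  $ co_ap_zero_percent : num 74.7
#>  $ co_ap_ge2_percent  : num 5.8
#>  $ n_dwt_eligible     : int 390

head(res$report$dwt_summary, 3)
#> # A tibble: 3 × 9
#>   molecule        n  mean    sd median    q1    q3   min   max
#>   <chr>       <int> <dbl> <dbl>  <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 risperidone    89  16.8  4.70   16.7  14.4  18.9  7.5   26.1
#> 2 cyamemazine    57  15.2  4.19   15.8  11.9  17.2  8.33  25
#> 3 tiapride       51  16.7  4.46   16.7  13.1  20.3  8.61  25
```

Reading this: of 500 simulated patients, 395 enter the cohort (the rest
never accumulate three consecutive months of the same molecule, are minors,
have a coverage hole in the lookback, or are followed under 12 months).
The cohort splits 152 FGAP / 182 SGAP primary antipsychotics — an SGAP/FGAP
ratio of 1.20, with percentages over the non-demoted denominator — and the
per-molecule adherence table shows mean first-year %DwT around 15–17%,
i.e. patients were without dispensed supply roughly one day in six. The
default simulation draws molecules and specialties in proportion to the
per-molecule counts published for the French 2007–2017 national cohort
(packaged in `inst/extdata/reference_pap_counts.csv`), so the synthetic
distribution resembles the national one.

A thin command-line dispatcher over the same functions is provided at
`inst/cli/apclaims.R`:

```sh
Rscript inst/cli/apclaims.R simulate --n 500 --seed 42 --out claims/
Rscript inst/cli/apclaims.R select-cohort --claims claims/ --out cohort.csv --exclusions excl.csv
Rscript inst/cli/apclaims.R assign-pap --claims claims/ --cohort cohort.csv --out pap.csv
Rscript inst/cli/apclaims.R metrics --claims claims/ --cohort cohort.csv --pap pap.csv --out exposure.csv
Rscript inst/cli/apclaims.R report --claims claims/ --cohort cohort.csv --pap pap.csv --exposure exposure.csv --out-dir reports/
```

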