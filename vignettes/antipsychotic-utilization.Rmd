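---
title: "Antipsychotic utilization and adherence from claims data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antipsychotic utilization and adherence from claims data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apclaims)
```

## The problem

Reimbursement-claims databases record every dispensing a patient collects at
a pharmacy, but not the prescribed dose, the indication, or whether the drug
was taken. Drug-utilization studies of antipsychotics therefore work with a
small set of derived quantities: who is chronically treated (as opposed to
receiving a one-off prescription), which molecule is a patient's *primary*
antipsychotic (PAP), how regularly it is refilled, what daily dose the
refills amount to, and how often other antipsychotics are co-dispensed.
`apclaims` implements this pipeline over a simplified schema modelled on the
French national health-insurance sample (EGB, a 1/97th random sample of the
reimbursement database): patient characteristics with month/year of birth,
coverage spells, chronic-disease (ALD) registrations, pharmacy dispensings,
and hospital ICD-10 diagnoses.

Because such databases cannot be redistributed, the package ships a seeded
synthetic-claims generator that emulates the schema's structure. Every
pipeline stage is exercised against it, and against small hand-built edge
cases, rather than against the real data.

## Cohort definition

A patient enters the cohort at the first dispensing of a run of **three
consecutive calendar months**, each containing at least one dispensing of
the same antipsychotic molecule (any form, oral or long-acting). This is a
strict calendar reading: dispensings on 31 January, 1 February and 1 March
qualify; January and March with an empty February do not. Year boundaries
are consecutive (December–January–February qualifies). The requirement
screens out punctual uses — emergency sedation, short symptomatic courses —
and anchors all downstream windows at the inclusion date.

The remaining criteria are applied in a fixed order, and every input
patient lands in exactly one of cohort or exclusions (`no_triple`,
`under_18`, `coverage_gap`, `short_followup`):

* age ≥ 18 years at inclusion. Claims carry only month and year of birth,
  so age is computed assuming birth on day 15 of the birth month, the
  convention that minimizes the maximum possible error;
* continuous insurance coverage over the 12 months before inclusion.
  Coverage spells are normalized (sorted, overlapping or touching spells
  merged); "continuity" tolerates administrative micro-gaps of at most
  `coverage_gap_tolerance_days` (default 0, the strict reading, exposed as
  configuration because the underlying databases do not define it). The
  source design also demands coverage over follow-up; this implementation
  checks the lookback only, a documented simplification — the synthetic
  generator injects its disqualifying gaps in the lookback window;
* at least 12 months (365 days) of follow-up.

Follow-up ends at the earliest of death, loss to follow-up, or the
administrative study end (default 2018-12-31). Loss to follow-up is
operationalized as the last antipsychotic dispensing preceding a gap of
more than 183 days (six months) with no further antipsychotic dispensing.
Two choices deserve note. First, the schema has no visit records, so
"antipsychotic-related care" is read as antipsychotic dispensings only.
Second, the gap is measured up to the next dispensing *or up to death or
study end when none follows*: a patient who dies a few weeks after their
last refill ends follow-up by death, not by an artifactual six-month gap
that their death interrupted.

## Primary antipsychotic assignment

When several molecules meet the three-month criterion, the primary
antipsychotic is the one dispensed for the longest period, measured as the
span from first to last dispensing within follow-up — the same definition
as the time-on-treatment outcome, which is why span rather than dispensing
count is the yardstick. Cyamemazine and levomepromazine are set aside
first: in France their indications and practical use target anxiety and
aggressiveness rather than psychosis, so they become the primary
antipsychotic only when nothing else qualifies. Span ties are broken by
the earlier first dispensing; residual ties are broken deterministically
(lexicographically smallest name) and flagged `needs_adjudication = TRUE`,
replacing the expert-panel adjudication of the original workflow with a
reproducible rule plus a review export for human override.

The packaged registry reproduces the French taxonomy: 20 first-generation
(FGAP) and 6 second-generation (SGAP) molecules plus the two demoted ones.
Amisulpride is deliberately classified as first-generation — the French
convention, although international usage often calls it atypical — because
fidelity to the national taxonomy governs the reproduction of its counts.
Long-acting availability is limited to haloperidol, risperidone,
paliperidone and aripiprazole; paliperidone is marketed only as
long-acting. The registry is a plain CSV and can be replaced wholesale for
other formularies.

## Adherence: percentage of days without treatment

The adherence statistic assumes every dispensing supplies 30 days of
treatment, regardless of quantity or dosage. Walking through the primary
antipsychotic's dispensings over the 12 months from the index dispensing,
each dispensing's theoretical date is the previous *actual* dispensing date
plus 30 days; a late dispensing adds the delay to the days-without-treatment
count, an early one adds nothing and does not bank supply. Days between the
end of the last dispensing's supply and the end of the window are also
untreated. Three numerical choices matter:

* **the window is 360 days** (12 supply periods), not 365. This is what
  makes the statistic's ceiling exactly 75%: the minimum three dispensings
  at 30-day spacing cover 90 of 360 days;
* **theoretical dates chain from actual dates**, not from previous
  theoretical dates. This reproduces both the no-stockpiling rule and the
  75% ceiling, and makes the gap walk exactly equivalent to
  100 × (window days not covered by the union of 30-day supply intervals) /
  window — an equivalence the test suite verifies against day-by-day
  enumeration on 1000 random dispensing sets;
* **the window is anchored at the first dispensing of the primary
  antipsychotic within follow-up** (and so is the 12-months-of-dispensing
  eligibility flag below). This equals the inclusion date whenever the
  primary molecule is the one that triggered inclusion — the overwhelmingly
  common case — and keeps the statistic well-defined when it is not.

Because adherence over a fixed first year is overestimated for patients who
stopped or switched early, the per-molecule adherence table is restricted
to patients whose primary antipsychotic was still dispensed at least 360
days after the anchor (`eligible_for_dwt_table`).

## Dispensed daily dose

The dispensed daily dose (DDD here; an empirical quantity, not the WHO
defined daily dose) averages the milligrams dispensed between one month
after inclusion and the last dispensing within the 12-month window. The
first month is excluded because dosing is commonly titrated early in
treatment. The implementation uses the half-open span
`[inclusion + 30, last)`: the final dispensing's own units are excluded
since their consumption falls outside the averaging span. The convention is
configurable (`ddd_include_last = TRUE` gives the closed-span reading); the
half-open default is the one under which patients consuming a constant
D mg/day with exact 30-day refills recover exactly D, which the tests
assert. "One month" is 30 days throughout, consistent with the supply
assumption, and time on treatment is converted to months at 30.44 days per
month (average calendar month; configurable).

## Co-dispensing, specialty, comorbidities

Co-dispensed antipsychotics are counted as distinct registry molecules,
other than the primary one, dispensed at least once within the primary
antipsychotic's first-to-last span. The demoted molecules count as
co-treatments. The span window is one documented reading of "co-treatment"
(the alternatives — any time in follow-up, or strict day-level overlap —
are narrower or wider); it is the package's fixed convention.

The prescriber specialty is taken from the index dispensing (first of the
day after a date-stable sort if several); unknown codes are reported as
`"unknown"`, never dropped. Comorbidities are flagged from hospital ICD-10
diagnoses in the half-open 12-month lookback `[inclusion − 365, inclusion)`
and from ALD registrations starting before inclusion, through a
configurable prefix map (defaults: chapter I → cardiovascular, chapter J →
respiratory, E10–E14 → diabetes, chapter F → psychiatric, ALD 23 →
psychotic disorder).

## Reporting conventions

Distribution tables report counts with percentages rounded to one decimal,
half away from zero. Every table carries its denominator and conserves it:
per-molecule counts sum to the cohort size, co-treatment bins
(0, 1, ..., 5, 6+) sum to the cohort size. The FGAP/SGAP split excludes the
demoted class from both numerator and denominator, and the SGAP/FGAP ratio
is reported unrounded alongside its constituent counts — printed
two-decimal ratios in the literature are ambiguous between rounding and
truncation, and the counts resolve the dispute. Numeric summaries use the
n / mean / SD / median / quartiles / min / max battery with type-7
(linearly interpolated) quantiles, a convention the source material does
not pin down; the tests check them against a hand-rolled interpolation.

## The synthetic generator

`simulation_config()` defaults define the emulated study conditions:
streams start uniformly over 2007–2017 and run to end 2018; ages are drawn
near the reported population profile (normal, mean 56, SD 19, clipped at
19–95, with a 2% minor fraction); the primary molecule is drawn in
proportion to the published national per-molecule counts (packaged as
`reference_pap_counts.csv`); prescriber specialties follow the published
shares; refill delays beyond the 30-day nominal interval are
`min(floor(Exponential(mean 7)), 180)` days, which puts the population mean
first-year %DwT near 16–20%, the range reported for antipsychotic cohorts;
dropout is 1% per 30-day month and death follows a 2%-per-year hazard at
age 65 scaled by `exp(0.07 (age − 65))` (held at the age at stream start),
giving the three follow-up-end reasons in realistic proportion; each
additional co-dispensed antipsychotic appears with geometric probability
0.3; 5% of patients carry a disqualifying 60-day coverage hole; 8% of
patients on a long-acting-capable molecule receive it as long-acting.
Dispensings are 30 units at a per-patient constant strength, i.e. one unit
per day of nominal supply.

The generator is renewal-style *by design*: because the adherence statistic
assumes 30-day supply, a renewal refill process makes exact adherence
expectations computable, so the pipeline can be tested for parameter
recovery rather than merely for plausibility. Two such oracles are used:

* the unconditional expectation of %DwT under the delay distribution, by a
  dynamic programme over the remaining window length — raw refill streams
  recover it;
* the expectation **conditioned on inclusion**. The three-consecutive-month
  rule is itself a selection on the refill process: given that the two
  calendar months after the anchor each received a dispensing, the first
  two post-anchor delays cannot have been large enough to skip a month.
  This truncation lowers the cohort mean %DwT below the naive renewal
  expectation by several tenths of a percentage point — a real, derivable
  selection effect, not a bug. The test suite computes the conditioned
  expectation exactly (a calendar-aware dynamic programme over
  month-occupancy states) and checks the cohort mean against it within
  three Monte-Carlo standard errors.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: dose titration and dose changes over time,
molecule switching (beyond incidental overtaking by a co-dispensed stream),
seasonal or weekday refill patterns, hospital stays interrupting community
dispensing, psychiatric-hospital dispensings (absent from the emulated
database itself), price/cost fields, and any correlation between adherence
and age, molecule, or comorbidity. The generator's purpose is structural
coverage and parameter recovery, not calibration to published real-data
tables, which are deliberately out of scope.

## Problem sizes and determinism

The test suite runs the full pipeline on 2,000 simulated patients for the
stochastic recovery check (about two minutes), 100–300 patients for the
deterministic recovery checks, and 1,000-case enumerations for the
%DwT-equivalence and assignment-rule oracles; these sizes give Monte-Carlo
standard errors around 0.1 percentage points, small enough to detect the
selection effect above. All simulation is seeded through the config and
leaves the caller's RNG state untouched; identical configs are
byte-identical.

## Known limitations

* The 30-day supply assumption is the field's convention for this
  statistic, but it misrepresents long-acting injectables dispensed at
  multi-week intervals; their adherence values should be read with care.
* The coverage-continuity check applies to the pre-inclusion lookback only
  (see above).
* A single primary antipsychotic per patient means switches appear as
  shortened time on treatment and inflated %DwT, which is why the adherence
  table is restricted to the 12-months-of-dispensing subset.
* Dose-equivalence (chlorpromazine-equivalent) conversion and ATC mapping
  are out of scope; the dispensed daily dose is reported in mg/day of the
  molecule itself.
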