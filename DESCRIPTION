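Package: apclaims
Title: Antipsychotic Utilization and Adherence Analysis for Claims Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for drug-utilization studies of antipsychotics in
    reimbursement-claims databases with an EGB-like schema (the 1/97th sample
    of the French national health-insurance database). Implements cohort
    selection based on three consecutive calendar months of dispensing of the
    same molecule, primary-antipsychotic assignment with longest-dispensed and
    first-dispensed rules, refill-gap adherence as the percentage of days
    without treatment under a 30-day supply assumption, dispensed-daily-dose
    estimation, antipsychotic co-dispensing counts, and descriptive reporting
    tables. A seeded synthetic-claims generator with controllable adherence,
    polypharmacy, coverage-gap, death and dropout processes makes every
    pipeline stage testable without access to the real database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lubridate,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
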