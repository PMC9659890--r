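d0 <- as.Date("2010-01-01")

test_that("%DwT is 0 for perfect 30-day refills and 75 for the bare minimum", {
  expect_equal(percent_days_without_treatment(d0 + seq(0, 330, by = 30)), 0)
  expect_equal(percent_days_without_treatment(d0 + c(0, 30, 60)), 75)
})

test_that("%DwT accumulates refill gaps plus the trailing uncovered period", {
  # gaps 15 + 0 + 75, trailing 150 -> 240/360
  expect_equal(
    percent_days_without_treatment(d0 + c(0, 45, 75, 180)),
    100 * 240 / 360
  )
})

test_that("early refills neither penalize nor bank supply", {
  # 20-day refills up to day 100, then an interval of 90 days (gap 60)
  dates <- d0 + c(seq(0, 100, by = 20), 190, seq(220, 340, by = 30))
  expect_equal(percent_days_without_treatment(dates), 100 * 60 / 360)
})

test_that("%DwT input validation rejects empty and unsorted dates", {
  expect_error(percent_days_without_treatment(as.Date(character())), "no dispensing")
  expect_error(
    percent_days_without_treatment(d0 + c(30, 0)), "sorted"
  )
})

test_that("gap walk equals the day-by-day coverage-union oracle", {
  withr::local_seed(314)
  for (rep in 1:1000) {
    dates <- random_date_set()
    expect_equal(
      percent_days_without_treatment(dates), brute_dwt(dates),
      info = paste("rep", rep)
    )
  }
})

test_that("%DwT is zero exactly when supply is gapless to the window end", {
  withr::local_seed(271)
  for (rep in 1:200) {
    dates <- random_date_set()
    d <- as.numeric(dates - dates[1])
    d <- d[d < 360]
    gapless <- all(diff(d) <= 30) && (d[length(d)] + 30 >= 360)
    expect_equal(
      percent_days_without_treatment(dates) == 0, gapless,
      info = paste("rep", rep)
    )
  }
})

test_that("any three dispensings >=30 days apart with none after give exactly 75", {
  withr::local_seed(99)
  for (rep in 1:50) {
    gaps <- 30 + sample(0:40, 2, replace = TRUE)
    dates <- d0 + cumsum(c(0, gaps))
    dates <- dates[as.numeric(dates - dates[1]) < 360]
    if (length(dates) == 3) {
      expect_equal(percent_days_without_treatment(dates), 75)
    }
  }
})

test_that("dispensed daily dose follows the half-open post-first-month span", {
  ev <- simple_dispensing("p1", d0 + c(0, 30, 60, 90), "olanzapine",
    units = 30, mg = 2
  )
  expect_equal(dispensed_daily_dose(ev, d0), 2) # 120 mg over 60 days
  ev2 <- simple_dispensing("p1", d0 + c(0, 40, 100), "olanzapine",
    units = 28, mg = 5
  )
  expect_equal(dispensed_daily_dose(ev2, d0), 2) # 140 mg over 70 days
})

test_that("dispensed daily dose is absent without post-first-month exposure", {
  expect_true(is.na(dispensed_daily_dose(
    simple_dispensing("p1", d0, "olanzapine"), d0
  )))
  expect_true(is.na(dispensed_daily_dose(
    simple_dispensing("p1", d0 + c(0, 20), "olanzapine"), d0
  )))
})

test_that("the closed-span option includes the final dispensing's units", {
  ev <- simple_dispensing("p1", d0 + c(0, 30, 60, 90), "olanzapine",
    units = 30, mg = 2
  )
  expect_equal(dispensed_daily_dose(ev, d0, include_last = TRUE), 180 / 60)
})

test_that("constant-dose 30-day refills recover the daily dose exactly", {
  ev <- simple_dispensing("p1", d0 + seq(0, 330, by = 30), "olanzapine",
    units = 30, mg = 10
  )
  expect_equal(dispensed_daily_dose(ev, d0), 10) # 30 units x 10 mg / 30 days
})

test_that("use summaries report months, mean interval and first-year units", {
  ev <- simple_dispensing("p1", d0 + c(0, 60), "olanzapine", units = 10)
  s <- summarize_pap_use(ev, d0)
  expect_equal(s$time_on_treatment_months, 60 / 30.44)
  expect_equal(s$mean_interval_days, 60)
  expect_equal(s$units_first_year, 20L)

  single <- summarize_pap_use(
    simple_dispensing("p1", d0, "olanzapine", units = 30), d0
  )
  expect_equal(single$time_on_treatment_months, 0)
  expect_true(is.na(single$mean_interval_days))
  expect_equal(single$units_first_year, 30L)

  s3 <- summarize_pap_use(
    simple_dispensing("p1", d0 + c(0, 40, 80), "olanzapine"), d0
  )
  expect_equal(s3$mean_interval_days, 40)
})

test_that("co-antipsychotic count is distinct molecules inside the PAP span", {
  ev <- dplyr::bind_rows(
    simple_dispensing("p1", d0 + c(0, 300), "risperidone"),
    simple_dispensing("p1", d0 + c(50, 200), "olanzapine"),
    simple_dispensing("p1", d0 + 100, "cyamemazine"),
    simple_dispensing("p1", d0 + 100, "paracetamol"), # not an antipsychotic
    simple_dispensing("p1", d0 + 400, "quetiapine") # outside the span
  )
  expect_equal(
    count_co_antipsychotics(ev, "risperidone", d0, d0 + 300), 2
  )
  # order-invariant, never counts the PAP molecule
  shuffled <- ev[sample(nrow(ev)), ]
  expect_equal(
    count_co_antipsychotics(shuffled, "risperidone", d0, d0 + 300), 2
  )
  expect_equal(
    count_co_antipsychotics(
      simple_dispensing("p1", d0 + c(0, 10), "risperidone"),
      "risperidone", d0, d0 + 300
    ), 0
  )
})

test_that("index-date prescriber specialty honours file order and unknowns", {
  ev <- dplyr::bind_rows(
    simple_dispensing("p1", d0, "olanzapine", specialty = "general_practitioner"),
    simple_dispensing("p1", d0, "olanzapine", specialty = "psychiatrist")
  )
  expect_equal(inclusion_prescriber_specialty(ev, d0), "general_practitioner")
  expect_error(
    inclusion_prescriber_specialty(ev, d0 + 1), "index"
  )
  unk <- simple_dispensing("p1", d0, "olanzapine", specialty = "unknown")
  expect_equal(inclusion_prescriber_specialty(unk, d0), "unknown")
})

test_that("comorbidities respect the 12-month lookback and ALD start rule", {
  map <- default_comorbidity_map()
  dx <- tibble::tibble(
    patient_id = "p1", date = d0 - 90, icd10_code = "I25"
  )
  expect_equal(
    identify_comorbidities(NULL, dx, d0, map), "cardiovascular"
  )
  dx_old <- tibble::tibble(
    patient_id = "p1", date = d0 - 430, icd10_code = "I25"
  )
  expect_equal(identify_comorbidities(NULL, dx_old, d0, map), character(0))
  ald <- tibble::tibble(patient_id = "p1", code = "23", start_date = d0 - 10)
  expect_equal(
    identify_comorbidities(ald, NULL, d0, map), "psychotic_disorder"
  )
  expect_error(
    identify_comorbidities(NULL, dx, d0, list(icd10 = c("9x" = "bad"), ald = c())),
    "malformed"
  )
})
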