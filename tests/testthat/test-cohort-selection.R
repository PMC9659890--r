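test_that("three dispensings in consecutive calendar months form one episode", {
  expect_equal(
    find_qualifying_episodes(as.Date(c("2010-01-15", "2010-02-10", "2010-03-20"))),
    as.Date("2010-01-15")
  )
})

test_that("a skipped calendar month breaks the episode", {
  expect_equal(
    find_qualifying_episodes(as.Date(c("2010-01-15", "2010-03-20"))),
    as.Date(character())
  )
})

test_that("December-January-February counts as consecutive months", {
  expect_equal(
    find_qualifying_episodes(as.Date(c("2009-12-30", "2010-01-05", "2010-02-27"))),
    as.Date("2009-12-30")
  )
})

test_that("episode finder agrees with month-triple enumeration on random streams", {
  withr::local_seed(2024)
  for (rep in 1:200) {
    n <- sample(1:40, 1)
    dates <- as.Date("2008-06-01") + sort(sample(0:1200, n, replace = TRUE))
    expect_equal(
      find_qualifying_episodes(dates), brute_triples(dates),
      info = paste("rep", rep)
    )
  }
})

test_that("follow-up ends at the earliest of death, refill gap, study end", {
  study_end <- as.Date("2018-12-31")
  # death during active refills
  fe <- determine_followup_end(
    as.Date("2012-01-01") + seq(0, 420, by = 30), as.Date("2012-03-01"),
    study_end
  )
  expect_equal(fe$followup_end, as.Date("2012-03-01"))
  expect_equal(fe$end_reason, "death")
  # long antipsychotic-free gap before study end
  fe <- determine_followup_end(
    as.Date(c("2012-03-01", "2012-05-01")), as.Date(NA), study_end
  )
  expect_equal(fe$followup_end, as.Date("2012-05-01"))
  expect_equal(fe$end_reason, "lost_to_followup")
  # refills continuing until close to study end
  fe <- determine_followup_end(
    seq(as.Date("2017-01-10"), as.Date("2018-12-10"), by = 30), as.Date(NA),
    study_end
  )
  expect_equal(fe$followup_end, study_end)
  expect_equal(fe$end_reason, "study_end")
})

test_that("a mid-stream gap over 183 days ends follow-up despite later refills", {
  dates <- as.Date(c("2010-01-01", "2010-02-01", "2011-06-01", "2011-07-01"))
  fe <- determine_followup_end(dates, as.Date(NA), as.Date("2018-12-31"))
  expect_equal(fe$followup_end, as.Date("2010-02-01"))
  expect_equal(fe$end_reason, "lost_to_followup")
})

test_that("death shortly after the last refill is death, not loss to follow-up", {
  fe <- determine_followup_end(
    as.Date(c("2012-01-01", "2012-02-01")), as.Date("2012-03-15"),
    as.Date("2018-12-31")
  )
  expect_equal(fe$end_reason, "death")
  expect_equal(fe$followup_end, as.Date("2012-03-15"))
})

test_that("follow-up end without any dispensing is an error", {
  expect_error(
    determine_followup_end(as.Date(character()), as.Date(NA), as.Date("2018-12-31")),
    "no antipsychotic dispensings"
  )
})

test_that("every patient lands in exactly one of cohort or exclusions", {
  claims <- simulate_population(simulation_config(n_patients = 60, seed = 8))
  sel <- select_cohort(claims)
  expect_equal(
    nrow(sel$cohort) + nrow(sel$exclusions), nrow(claims$patients)
  )
  expect_false(any(sel$cohort$patient_id %in% sel$exclusions$patient_id))
  # included members satisfy the documented invariants
  expect_true(all(sel$cohort$age_at_inclusion >= 18))
  expect_true(all(
    as.numeric(sel$cohort$followup_end - sel$cohort$inclusion_date) >= 365
  ))
  cfg <- study_config()
  expect_true(all(sel$cohort$inclusion_date >= cfg$study_start &
    sel$cohort$inclusion_date <= cfg$inclusion_end))
})

test_that("an episode starting after the inclusion window is not an inclusion", {
  patients <- tibble::tibble(
    patient_id = "p1", birth_year = 1970L, birth_month = 6L, sex = "male",
    death_date = as.Date(NA), free_access = FALSE
  )
  coverage <- tibble::tibble(
    patient_id = "p1", start_date = as.Date("2005-01-01"),
    end_date = as.Date("2018-12-31")
  )
  disp <- simple_dispensing(
    "p1", as.Date("2018-06-01") + 30 * (0:5), "olanzapine"
  )
  claims <- make_claims(
    patients = patients, coverage = coverage, dispensings = disp
  )
  sel <- select_cohort(claims)
  expect_equal(sel$exclusions$reason, "no_triple")
})

test_that("extra dispensings of the qualifying molecule never delay inclusion", {
  withr::local_seed(303)
  patients <- tibble::tibble(
    patient_id = "p1", birth_year = 1960L, birth_month = 1L, sex = "female",
    death_date = as.Date(NA), free_access = FALSE
  )
  coverage <- tibble::tibble(
    patient_id = "p1", start_date = as.Date("2005-01-01"),
    end_date = as.Date("2018-12-31")
  )
  for (rep in 1:40) {
    base_dates <- as.Date("2010-03-01") +
      sort(sample(0:900, sample(3:15, 1)))
    extra <- as.Date("2010-03-01") + sample(0:900, sample(1:5, 1))
    sel1 <- select_cohort(make_claims(
      patients = patients, coverage = coverage,
      dispensings = simple_dispensing("p1", base_dates, "haloperidol")
    ))
    sel2 <- select_cohort(make_claims(
      patients = patients, coverage = coverage,
      dispensings = simple_dispensing(
        "p1", sort(c(base_dates, extra)), "haloperidol"
      )
    ))
    if (nrow(sel1$cohort) == 1L) {
      expect_equal(nrow(sel2$cohort), 1L)
      expect_lte(sel2$cohort$inclusion_date, sel1$cohort$inclusion_date)
    }
  }
})
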