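test_that("numeric summaries match brute-force interpolated quantiles", {
  withr::local_seed(42)
  for (rep in 1:50) {
    x <- stats::rnorm(sample(1:40, 1), mean = 20, sd = 10)
    s <- numeric_summary(x)
    expect_equal(s$n, length(x))
    expect_equal(s$median, brute_quantile(x, 0.5))
    expect_equal(s$q1, brute_quantile(x, 0.25))
    expect_equal(s$q3, brute_quantile(x, 0.75))
    expect_true(s$min <= s$q1 && s$q1 <= s$median &&
      s$median <= s$q3 && s$q3 <= s$max)
  }
})

test_that("numeric summaries handle singletons and missing values", {
  s <- numeric_summary(c(5, NA))
  expect_equal(s$n, 1L)
  expect_true(is.na(s$sd))
  expect_equal(s$min, s$max)
  expect_equal(numeric_summary(rep(NA_real_, 3))$n, 0L)
  hand <- numeric_summary(c(0, 30, 60))
  expect_equal(hand$mean, 30)
  expect_equal(hand$median, 30)
  expect_equal(hand$min, 0)
  expect_equal(hand$max, 60)
})

test_that("percent rounding is half-away-from-zero to one decimal", {
  expect_equal(apclaims:::round_half_up(65.75, 1), 65.8)
  expect_equal(apclaims:::round_half_up(14.747, 1), 14.7)
  expect_equal(apclaims:::round_half_up(-2.35, 1), -2.4)
})

test_that("PAP distribution conserves the cohort and covers zero rows", {
  assignments <- tibble::tibble(
    pap_molecule = c("risperidone", "risperidone", "cyamemazine")
  )
  dist <- pap_distribution(assignments)
  expect_equal(sum(dist$count), 3L)
  expect_equal(nrow(dist), nrow(ap_registry()))
  expect_equal(dist$percent[dist$molecule == "risperidone"], 66.7)
  expect_true(all(dist$count[dist$molecule == "droperidol"] == 0))
  expect_error(
    pap_distribution(tibble::tibble(pap_molecule = "aspirin")),
    class = "apclaims_not_antipsychotic"
  )
})

test_that("generation split excludes the OTHER class from both sides", {
  toy <- tibble::tibble(
    pap_molecule = c("haloperidol", "risperidone", "cyamemazine")
  )
  gs <- generation_split(toy)
  expect_equal(gs$fgap_count, 1L)
  expect_equal(gs$sgap_count, 1L)
  expect_equal(gs$ratio, 1)
  expect_equal(gs$denominator, 2L)

  all_sgap <- generation_split(tibble::tibble(pap_molecule = "olanzapine"))
  expect_equal(all_sgap$fgap_count, 0L)
  expect_true(is.na(all_sgap$ratio))
})

test_that("long-acting share counts patients with an in-span long-acting event", {
  assignments <- tibble::tibble(
    patient_id = c("a", "b", "c"),
    pap_molecule = c("risperidone", "risperidone", "haloperidol"),
    pap_first_date = as.Date("2010-01-01"),
    pap_last_date = as.Date("2010-12-31")
  )
  disp <- dplyr::bind_rows(
    simple_dispensing("a", as.Date("2010-05-01"), "risperidone",
      form = "long_acting"
    ),
    simple_dispensing("b", as.Date("2010-05-01"), "risperidone"),
    # long-acting but outside the PAP span
    simple_dispensing("c", as.Date("2011-05-01"), "haloperidol",
      form = "long_acting"
    )
  )
  la <- long_acting_share(assignments, disp)
  expect_equal(la$count[la$molecule == "total"], 1L)
  expect_equal(la$count[la$molecule == "risperidone"], 1L)
  expect_false("haloperidol" %in% la$molecule)
})

test_that("co-treatment bins conserve patients and report the >=2 share", {
  exposures <- tibble::tibble(n_co_aps = c(0L, 0L, 1L, 2L, 7L))
  ct <- co_treatment_table(exposures)
  expect_equal(sum(ct$count), 5L)
  expect_equal(ct$count[ct$n_co_aps == "6+"], 1L)
  expect_equal(attr(ct, "share_ge2"), 40)
  all_zero <- co_treatment_table(tibble::tibble(n_co_aps = rep(0L, 4)))
  expect_equal(all_zero$percent[all_zero$n_co_aps == "0"], 100)
})

test_that("per-molecule summaries pool the right metric and denominators", {
  exposures <- tibble::tibble(
    patient_id = c("a", "b", "c"),
    pap_molecule = "olanzapine",
    pct_dwt = c(0, 30, 60),
    ddd_mg_per_day = c(10, NA, 20),
    time_on_treatment_months = c(1, 2, 3),
    mean_interval_days = c(30, 31, 32),
    units_first_year = c(360L, 300L, 200L),
    eligible_for_dwt_table = c(TRUE, TRUE, FALSE)
  )
  dwt <- per_pap_summaries(NULL, NULL, exposures, "dwt")
  expect_equal(dwt$n, 2L) # the day-200 stopper is excluded
  expect_equal(dwt$mean, 15)
  ddd <- per_pap_summaries(NULL, NULL, exposures, "ddd")
  expect_equal(ddd$n, 2L) # missing DDD excluded from n
  expect_equal(ddd$mean, 15)
  tot <- per_pap_summaries(NULL, NULL, exposures, "time_on_treatment")
  expect_equal(tot$n, 3L)
})

test_that("the full report assembles and writes its files", {
  claims <- simulate_population(simulation_config(n_patients = 80, seed = 21))
  dir <- withr::local_tempdir()
  res <- run_ap_pipeline(claims, out_dir = dir)
  expect_true(file.exists(file.path(dir, "pap_distribution.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  s <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(s$n_cohort, nrow(res$cohort))
  expect_equal(sum(res$report$pap_distribution$count), nrow(res$cohort))
  expect_equal(sum(res$report$co_treatment$count), nrow(res$cohort))
})
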