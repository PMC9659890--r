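#' Fixed edge-case fixture population
#'
#' A small, fully deterministic population with one patient per pipeline
#' branch, for tests and worked examples. Patient ids name the branch:
#'
#' * `under_18` -- a 16-year-old with an otherwise qualifying stream;
#'   excluded `under_18`.
#' * `two_month_streak` -- dispensings in two consecutive months only;
#'   excluded `no_triple`.
#' * `month_skip` -- dispensings in alternating months (never three
#'   consecutive); excluded `no_triple`.
#' * `coverage_gap` -- qualifying stream but a 60-day insurance hole about
#'   four months before inclusion; excluded `coverage_gap`.
#' * `short_followup` -- exactly three dispensings then nothing; follow-up
#'   ends at the third dispensing (loss to follow-up), under 12 months;
#'   excluded `short_followup`.
#' * `death_mid_followup` -- monthly refills until death about 17 months
#'   in; included, `end_reason = "death"`. Carries a pre-inclusion I25
#'   hospital diagnosis (cardiovascular comorbidity).
#' * `cyamemazine_only` -- only cyamemazine qualifies, so it is the primary
#'   antipsychotic despite its demoted class. Carries an ALD 23
#'   (psychotic-disorder) registration.
#' * `tie_patient` -- two molecules dispensed on identical dates: equal
#'   spans and first dates force the deterministic tie-break and
#'   `needs_adjudication = TRUE`.
#' * `early_refill` -- a stockpiling patient: six refills 20 days apart,
#'   then a 90-day interval (60 days beyond the 30-day supply), then
#'   monthly; early refills bank no supply, so first-year %DwT is
#'   60/360 = 16.67%.
#'
#' @return An `ap_claims` object.
#' @examples
#' ec <- simulate_edge_cases()
#' select_cohort(ec)$exclusions
#' @export
simulate_edge_cases <- function() {
  d <- function(x) as.Date(x)
  monthly <- function(start, n) d(start) + 30L * (0:(n - 1L))

  disp <- function(pid, dates, molecule, units = 30L, mg = 2,
                   specialty = "general_practitioner", form = "oral") {
    tibble(
      patient_id = pid, date = dates, molecule = molecule, form = form,
      units = units, mg_per_unit = mg, prescriber_specialty = specialty
    )
  }
  pat <- function(pid, birth_year, birth_month = 6L, sex = "female",
                  death_date = as.Date(NA), free_access = FALSE) {
    tibble(
      patient_id = pid, birth_year = as.integer(birth_year),
      birth_month = as.integer(birth_month), sex = sex,
      death_date = death_date, free_access = free_access
    )
  }
  cov <- function(pid, start = "2005-01-01", end = "2018-12-31") {
    tibble(patient_id = pid, start_date = d(start), end_date = d(end))
  }

  patients <- bind_rows(
    pat("coverage_gap", 1970),
    pat("cyamemazine_only", 1965, sex = "male"),
    pat("death_mid_followup", 1950, death_date = d("2011-06-20")),
    pat("early_refill", 1980),
    pat("month_skip", 1975, sex = "male"),
    pat("short_followup", 1985),
    pat("tie_patient", 1972, sex = "male"),
    pat("two_month_streak", 1968),
    pat("under_18", 1993, birth_month = 6L)
  )

  dispensings <- bind_rows(
    disp("coverage_gap", monthly("2010-01-15", 14), "olanzapine"),
    disp("cyamemazine_only", monthly("2010-01-10", 14), "cyamemazine"),
    disp("death_mid_followup", monthly("2010-01-10", 18), "haloperidol",
      specialty = "psychiatrist"
    ),
    disp(
      "early_refill",
      d("2010-01-10") + c(
        0L, 20L, 40L, 60L, 80L, 100L, 190L, 220L, 250L,
        280L, 310L, 340L, 370L, 400L, 430L, 460L
      ),
      "risperidone"
    ),
    disp("month_skip", d("2010-01-10") + c(0L, 59L, 120L, 181L), "risperidone"),
    disp("short_followup", monthly("2010-01-10", 3), "quetiapine"),
    disp("tie_patient", monthly("2010-01-10", 14), "aripiprazole"),
    disp("tie_patient", monthly("2010-01-10", 14), "olanzapine"),
    disp("two_month_streak", monthly("2010-01-10", 2), "haloperidol"),
    disp("under_18", monthly("2010-01-10", 14), "olanzapine")
  ) |> arrange(.data$patient_id, .data$date)

  coverage <- bind_rows(
    cov("coverage_gap", end = "2009-08-31"),
    cov("coverage_gap", start = "2009-10-31"),
    cov("cyamemazine_only"), cov("death_mid_followup"), cov("early_refill"),
    cov("month_skip"), cov("short_followup"), cov("tie_patient"),
    cov("two_month_streak"), cov("under_18")
  ) |> arrange(.data$patient_id, .data$start_date)

  ald <- tibble(
    patient_id = "cyamemazine_only", code = "23", start_date = d("2009-01-01")
  )
  diagnoses <- tibble(
    patient_id = "death_mid_followup", date = d("2009-11-10"),
    icd10_code = "I25"
  )

  new_claims(patients, ald, coverage, dispensings, diagnoses)
}
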