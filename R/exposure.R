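#' Percentage of days without treatment (%DwT)
#'
#' Refill-gap adherence over a 12-month window, under the convention that
#' every dispensing supplies 30 days of treatment regardless of the quantity
#' or dosage dispensed. Walking through the dispensings in date order, each
#' dispensing's theoretical date is the previous actual dispensing date plus
#' 30 days; a dispensing after its theoretical date adds the days in between
#' to the days-without-treatment total, while a dispensing on or before its
#' theoretical date adds nothing -- early refills do not bank supply. Days
#' between the end of the last dispensing's 30-day supply and the end of the
#' window are also without treatment. The result is the total as a
#' percentage of the window.
#'
#' The window is 360 days (12 30-day supply periods). With the minimum of
#' three dispensings required for inclusion, the statistic's ceiling is
#' exactly 75% (three dispensings at 30-day spacing cover 90 of 360 days);
#' a 365-day window would not give a round ceiling.
#'
#' The gap-accumulation walk is equivalent to 100 x (window days not covered
#' by the union of the per-dispensing 30-day supply intervals) / window.
#'
#' @param pap_dates Dates of the primary antipsychotic's dispensings, sorted
#'   ascending, the first being the start of the adherence window (the
#'   inclusion dispensing). Dates on or after `first + window_days` are
#'   ignored.
#' @param window_days Adherence window length in days; default 360.
#' @return The percentage, a number in `[0, 100)`.
#' @examples
#' percent_days_without_treatment(as.Date("2010-01-01") + c(0, 30, 60)) # 75
#' @export
percent_days_without_treatment <- function(pap_dates, window_days = 360L) {
  if (length(pap_dates) == 0L) abort("no dispensing dates")
  d <- as.numeric(as_iso_date(pap_dates))
  if (anyNA(d)) abort("unparseable dispensing dates")
  if (is.unsorted(d)) abort("dispensing dates must be sorted ascending")
  d <- d - d[1]
  d <- d[d < window_days]
  gaps <- if (length(d) > 1L) pmax(0, diff(d) - 30) else numeric(0)
  trailing <- max(0, window_days - (d[length(d)] + 30))
  100 * (sum(gaps) + trailing) / window_days
}

#' Dispensed daily dose (DDD), in mg per day
#'
#' Average dose dispensed between one month after inclusion and the last
#' dispensing within the 12-month window: the milligrams dispensed
#' (units x mg per unit) from day 30 up to, but excluding, the last in-window
#' dispensing date `L`, divided by the days from day 30 to `L`. The first
#' month is left out because dosing is commonly titrated early in treatment.
#' The final dispensing's own units are excluded by default, since their
#' consumption falls outside the averaging span; set `include_last = TRUE`
#' for the closed-span convention. The dose is undefined (`NA`) when the
#' last in-window dispensing is within the first month or no dispensing
#' falls in the span. This "dispensed daily dose" is an empirical quantity,
#' distinct from the WHO defined daily dose.
#'
#' @param pap_events Tibble of the primary antipsychotic's dispensings:
#'   `date`, `units`, `mg_per_unit`.
#' @param inclusion Inclusion date (start of the 12-month window).
#' @param window_days Window length in days; default 360.
#' @param include_last Include the last dispensing's units in the numerator
#'   (default `FALSE`).
#' @return mg/day, or `NA_real_` when undefined.
#' @export
dispensed_daily_dose <- function(pap_events, inclusion, window_days = 360L,
                                 include_last = FALSE) {
  inclusion <- as_iso_date(inclusion)
  ev <- pap_events |>
    filter(.data$date >= inclusion, .data$date < inclusion + window_days) |>
    arrange(.data$date)
  if (nrow(ev) == 0L) {
    return(NA_real_)
  }
  last_date <- max(ev$date)
  span_start <- inclusion + 30L
  if (last_date <= span_start) {
    return(NA_real_)
  }
  in_span <- ev$date >= span_start & (if (include_last) {
    ev$date <= last_date
  } else {
    ev$date < last_date
  })
  if (!any(in_span)) {
    return(NA_real_)
  }
  mg <- sum(ev$units[in_span] * ev$mg_per_unit[in_span])
  mg / as.numeric(last_date - span_start)
}

#' Summaries of primary-antipsychotic use
#'
#' Time on treatment (months between first and last dispensing over the full
#' follow-up, at 30.44 days per month), mean interval between consecutive
#' dispensings over the first 12 months, and units dispensed over the first
#' 12 months.
#'
#' @param pap_events Tibble of the primary antipsychotic's dispensings within
#'   follow-up: `date`, `units`.
#' @param inclusion Inclusion date anchoring the 12-month (360-day) window.
#' @param window_days First-year window in days; default 360.
#' @param days_per_month Month length for the time-on-treatment conversion;
#'   default 30.44 (average calendar month).
#' @return List with `time_on_treatment_months`, `mean_interval_days`
#'   (`NA` with fewer than two in-window dispensings), `units_first_year`.
#' @export
summarize_pap_use <- function(pap_events, inclusion, window_days = 360L,
                              days_per_month = 30.44) {
  stopifnot(nrow(pap_events) >= 1L)
  inclusion <- as_iso_date(inclusion)
  dates <- sort(pap_events$date)
  first_year <- pap_events |>
    filter(.data$date >= inclusion, .data$date < inclusion + window_days) |>
    arrange(.data$date)
  list(
    time_on_treatment_months =
      as.numeric(max(dates) - min(dates)) / days_per_month,
    mean_interval_days = if (nrow(first_year) >= 2L) {
      mean(as.numeric(diff(first_year$date)))
    } else {
      NA_real_
    },
    units_first_year = as.integer(sum(first_year$units))
  )
}

#' Count co-dispensed antipsychotics
#'
#' Number of distinct registry molecules, other than the primary
#' antipsychotic, with at least one dispensing dated within the primary
#' antipsychotic's first-to-last dispensing span. Cyamemazine and
#' levomepromazine count as co-treatments here even though they are demoted
#' in primary-antipsychotic assignment.
#'
#' @param all_events All the patient's dispensing events (`date`,
#'   `molecule`).
#' @param pap_molecule Primary antipsychotic molecule.
#' @param pap_first,pap_last Span bounds (closed interval).
#' @param registry Registry tibble.
#' @return Non-negative integer count of distinct molecules.
#' @export
count_co_antipsychotics <- function(all_events, pap_molecule, pap_first,
                                    pap_last, registry = ap_registry()) {
  mols <- tolower(all_events$molecule)
  keep <- mols != tolower(pap_molecule) &
    is_antipsychotic(mols, registry) &
    all_events$date >= pap_first & all_events$date <= pap_last
  length(unique(mols[keep]))
}

#' Prescriber specialty at the index dispensing
#'
#' Specialty of the primary antipsychotic's dispensing on the index date
#' (several same-day dispensings resolve to the first after a date-stable
#' sort, i.e. original file order within the day). Unknown specialty codes
#' are reported as `"unknown"`, never dropped.
#'
#' @param pap_events The primary antipsychotic's dispensings
#'   (`date`, `prescriber_specialty`), in file order.
#' @param index_date The dispensing date anchoring the assignment (the
#'   inclusion dispensing).
#' @return A specialty string.
#' @export
inclusion_prescriber_specialty <- function(pap_events, index_date) {
  hit <- pap_events$prescriber_specialty[pap_events$date == as_iso_date(index_date)]
  if (length(hit) == 0L) {
    abort("no dispensing on the index date; the index is defined by that dispensing")
  }
  sp <- hit[1]
  if (!sp %in% specialty_levels) sp <- "unknown"
  sp
}

#' Default comorbidity code map
#'
#' Maps ICD-10 code prefixes (hospital diagnoses) and chronic-disease (ALD)
#' codes to comorbidity labels. The default is deliberately coarse: chapter-I
#' codes to cardiovascular disease, chapter-J to respiratory disease,
#' E10-E14 to diabetes, chapter-F to psychiatric disorder, and ALD code 23
#' (psychotic disorders) plus ALD 8 (diabetes) on the chronic-disease side.
#'
#' @return A list with character vectors `icd10` (names = prefixes,
#'   values = labels) and `ald` (names = ALD codes, values = labels).
#' @export
default_comorbidity_map <- function() {
  list(
    icd10 = c(
      "I" = "cardiovascular", "J" = "respiratory",
      "E10" = "diabetes", "E11" = "diabetes", "E12" = "diabetes",
      "E13" = "diabetes", "E14" = "diabetes", "F" = "psychiatric"
    ),
    ald = c("23" = "psychotic_disorder", "8" = "diabetes")
  )
}

validate_code_map <- function(code_map) {
  if (!is.list(code_map) || !all(c("icd10", "ald") %in% names(code_map))) {
    abort("code map must be a list with elements 'icd10' and 'ald'")
  }
  bad <- names(code_map$icd10)[!grepl("^[A-Z][0-9]*$", names(code_map$icd10))]
  if (length(bad) > 0L) {
    abort(sprintf(
      "malformed ICD-10 prefix(es) in code map: %s",
      paste(bad, collapse = ", ")
    ))
  }
  invisible(code_map)
}

#' Identify comorbidities in the pre-inclusion lookback
#'
#' A comorbidity label is flagged when a hospital diagnosis dated within the
#' 12 months before inclusion (the half-open interval
#' `[inclusion - lookback_days, inclusion)`) matches one of the map's ICD-10
#' prefixes, or when a chronic-disease (ALD) registration with a mapped code
#' starts before inclusion.
#'
#' @param ald_records The patient's ALD records (`code`, `start_date`).
#' @param diagnoses The patient's hospital diagnoses (`date`, `icd10_code`).
#' @param inclusion Inclusion date.
#' @param code_map Code map as in [default_comorbidity_map()]; validated at
#'   load time, malformed prefixes are a hard error.
#' @param lookback_days Lookback window in days; default 365.
#' @return Sorted character vector of distinct labels (possibly empty).
#' @export
identify_comorbidities <- function(ald_records, diagnoses, inclusion,
                                   code_map = default_comorbidity_map(),
                                   lookback_days = 365L) {
  validate_code_map(code_map)
  inclusion <- as_iso_date(inclusion)
  labels <- character(0)
  if (!is.null(diagnoses) && nrow(diagnoses) > 0L) {
    dx <- diagnoses |>
      filter(.data$date >= inclusion - lookback_days, .data$date < inclusion)
    for (prefix in names(code_map$icd10)) {
      if (any(startsWith(dx$icd10_code, prefix))) {
        labels <- c(labels, code_map$icd10[[prefix]])
      }
    }
  }
  if (!is.null(ald_records) && nrow(ald_records) > 0L) {
    ald <- ald_records |> filter(.data$start_date < inclusion)
    hit <- as.character(ald$code) %in% names(code_map$ald)
    labels <- c(labels, unname(code_map$ald[as.character(ald$code[hit])]))
  }
  sort(unique(labels))
}

#' Per-patient exposure summaries for a cohort
#'
#' Runs every exposure metric for each cohort member with an assigned
#' primary antipsychotic (PAP): %DwT ([percent_days_without_treatment]),
#' dispensed daily dose ([dispensed_daily_dose]), time on treatment, mean
#' inter-dispensing interval and first-year units ([summarize_pap_use]),
#' co-dispensed antipsychotic count ([count_co_antipsychotics]), prescriber
#' specialty at the PAP's index dispensing, and comorbidity flags
#' ([identify_comorbidities]).
#'
#' The adherence window (and the 12-months-of-dispensing eligibility flag
#' `eligible_for_dwt_table`) is anchored at the PAP's first dispensing within
#' follow-up; this equals the cohort inclusion date whenever the PAP is the
#' molecule that triggered inclusion, the common case. The dispensed daily
#' dose keeps the inclusion-date anchor of its definition.
#'
#' @param claims An `ap_claims` object.
#' @param cohort Cohort tibble from [select_cohort()].
#' @param assignments Assignment tibble from [assign_pap_cohort()].
#' @param registry Registry tibble.
#' @param window_days Adherence / first-year window (days); default 360.
#' @param code_map Comorbidity code map.
#' @param ddd_include_last Passed to [dispensed_daily_dose()].
#' @return Tibble with one row per patient: `patient_id`, `pap_molecule`,
#'   `pct_dwt`, `ddd_mg_per_day`, `time_on_treatment_months`,
#'   `mean_interval_days`, `units_first_year`, `n_co_aps`,
#'   `prescriber_specialty`, `comorbidities` (`;`-separated, possibly
#'   empty), `eligible_for_dwt_table`.
#' @export
compute_exposures <- function(claims, cohort, assignments,
                              registry = ap_registry(), window_days = 360L,
                              code_map = default_comorbidity_map(),
                              ddd_include_last = FALSE) {
  validate_code_map(code_map)
  disp_by_patient <- split(claims$dispensings, claims$dispensings$patient_id)
  dx_by_patient <- split(claims$diagnoses, claims$diagnoses$patient_id)
  ald_by_patient <- split(claims$ald, claims$ald$patient_id)
  joined <- dplyr::inner_join(cohort, assignments, by = "patient_id")

  purrr::map(seq_len(nrow(joined)), function(i) {
    m <- joined[i, ]
    events <- disp_by_patient[[m$patient_id]]
    in_followup <- events$date >= m$inclusion_date &
      events$date <= m$followup_end
    pap_events <- events[in_followup &
      tolower(events$molecule) == m$pap_molecule, ]
    anchor <- min(pap_events$date)
    dwt_dates <- sort(pap_events$date[pap_events$date < anchor + window_days])
    use <- summarize_pap_use(pap_events, m$inclusion_date, window_days)
    tibble(
      patient_id = m$patient_id,
      pap_molecule = m$pap_molecule,
      pct_dwt = percent_days_without_treatment(dwt_dates, window_days),
      ddd_mg_per_day = dispensed_daily_dose(
        pap_events, m$inclusion_date, window_days, ddd_include_last
      ),
      time_on_treatment_months = use$time_on_treatment_months,
      mean_interval_days = use$mean_interval_days,
      units_first_year = use$units_first_year,
      n_co_aps = count_co_antipsychotics(
        events[in_followup, ], m$pap_molecule,
        m$pap_first_date, m$pap_last_date, registry
      ),
      prescriber_specialty = inclusion_prescriber_specialty(pap_events, anchor),
      comorbidities = paste(
        identify_comorbidities(
          ald_by_patient[[m$patient_id]], dx_by_patient[[m$patient_id]],
          m$inclusion_date, code_map
        ),
        collapse = ";"
      ),
      eligible_for_dwt_table =
        max(pap_events$date) >= anchor + window_days
    )
  }) |> bind_rows()
}
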