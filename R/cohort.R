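#' Study configuration
#'
#' Bundles the study-window and eligibility parameters used by
#' [select_cohort()] and downstream metrics.
#'
#' @param study_start,inclusion_end First and last dates on which an inclusion
#'   episode may start (defaults 2007-01-01 and 2017-12-31).
#' @param study_end Administrative end of follow-up (default 2018-12-31).
#' @param min_age Minimum age (completed years) at inclusion; default 18.
#' @param lookback_days Continuous-coverage lookback before inclusion, in
#'   days; default 365.
#' @param min_followup_days Minimum follow-up length, in days; default 365.
#' @param followup_gap_days Length of the antipsychotic-free period after
#'   which follow-up is considered ended (loss to follow-up); default 183
#'   days, the 6-month reading.
#' @param coverage_gap_tolerance_days Administrative micro-gap still counted
#'   as continuous coverage; default 0 (strict).
#' @return A list of class `ap_study_config`.
#' @export
study_config <- function(study_start = as.Date("2007-01-01"),
                         inclusion_end = as.Date("2017-12-31"),
                         study_end = as.Date("2018-12-31"),
                         min_age = 18L,
                         lookback_days = 365L,
                         min_followup_days = 365L,
                         followup_gap_days = 183L,
                         coverage_gap_tolerance_days = 0L) {
  cfg <- list(
    study_start = as_iso_date(study_start),
    inclusion_end = as_iso_date(inclusion_end),
    study_end = as_iso_date(study_end),
    min_age = as.integer(min_age),
    lookback_days = as.integer(lookback_days),
    min_followup_days = as.integer(min_followup_days),
    followup_gap_days = as.integer(followup_gap_days),
    coverage_gap_tolerance_days = as.integer(coverage_gap_tolerance_days)
  )
  stopifnot(
    cfg$study_start <= cfg$inclusion_end,
    cfg$inclusion_end <= cfg$study_end
  )
  structure(cfg, class = "ap_study_config")
}

#' Find qualifying three-consecutive-month episodes
#'
#' An inclusion episode for a molecule is a run of three consecutive calendar
#' months (m, m+1, m+2) each containing at least one dispensing of that
#' molecule, in any form. Year boundaries count as consecutive
#' (December-January-February qualifies). The episode start is the date of
#' the first dispensing in the first month of the triple. This is a strict
#' calendar-month reading: Jan 31 / Feb 1 / Mar 1 qualifies, while
#' dispensings in January and March with none in February do not.
#'
#' @param dates Dispensing dates of one molecule for one patient (sorted or
#'   not; they are sorted internally).
#' @return Sorted `Date` vector of episode start dates, one per qualifying
#'   month triple; empty when no triple exists.
#' @examples
#' find_qualifying_episodes(as.Date(c("2009-12-30", "2010-01-05", "2010-02-27")))
#' @export
find_qualifying_episodes <- function(dates) {
  if (length(dates) == 0L) {
    return(as.Date(character()))
  }
  dates <- sort(as_iso_date(dates))
  mi <- month_index(dates)
  months <- unique(mi)
  triple_start_months <- months[(months + 1L) %in% months & (months + 2L) %in% months]
  if (length(triple_start_months) == 0L) {
    return(as.Date(character()))
  }
  sort(as.Date(vapply(
    triple_start_months,
    function(m) min(dates[mi == m]),
    numeric(1)
  ), origin = "1970-01-01"))
}

#' Determine the end of follow-up
#'
#' Follow-up ends at the earliest of: (i) the date of death; (ii) the last
#' antipsychotic dispensing preceding an antipsychotic-free period longer
#' than `gap_days` days (loss to follow-up); (iii) the administrative study
#' end. The antipsychotic-free period is measured up to the next dispensing,
#' or up to death or the study end when no dispensing follows -- so a patient
#' who dies shortly after a dispensing ends follow-up by death, not by loss
#' to follow-up.
#'
#' @param ap_dates Sorted dates of all the patient's antipsychotic
#'   dispensings (any registry molecule).
#' @param death_date Date of death or `NA`.
#' @param study_end Administrative study end date.
#' @param gap_days Gap threshold in days (default 183, the 6-month reading).
#' @return A list with `followup_end` (Date) and `end_reason` (one of
#'   `"death"`, `"lost_to_followup"`, `"study_end"`).
#' @export
determine_followup_end <- function(ap_dates, death_date, study_end,
                                   gap_days = 183L) {
  if (length(ap_dates) == 0L) {
    abort("patient has no antipsychotic dispensings; follow-up end is undefined")
  }
  ap_dates <- sort(as_iso_date(ap_dates))
  study_end <- as_iso_date(study_end)
  death_date <- as_iso_date(death_date)
  horizon <- study_end
  if (!is.na(death_date) && death_date < horizon) horizon <- death_date
  upto <- ap_dates[ap_dates <= horizon]
  if (length(upto) == 0L) upto <- ap_dates[1]
  nxt <- c(upto[-1], horizon)
  gaps <- as.numeric(nxt - upto)
  idx <- which(gaps > gap_days)
  candidates <- tibble(
    followup_end = as.Date(character()), end_reason = character()
  )
  if (!is.na(death_date) && death_date <= study_end) {
    candidates <- bind_rows(candidates, tibble(
      followup_end = death_date, end_reason = "death"
    ))
  }
  if (length(idx) > 0L) {
    candidates <- bind_rows(candidates, tibble(
      followup_end = upto[min(idx)], end_reason = "lost_to_followup"
    ))
  }
  candidates <- bind_rows(candidates, tibble(
    followup_end = study_end, end_reason = "study_end"
  ))
  best <- candidates[order(candidates$followup_end), ][1, ]
  list(followup_end = best$followup_end, end_reason = best$end_reason)
}

#' Select the study cohort
#'
#' Applies the inclusion and exclusion cascade to every patient:
#'
#' 1. at least one qualifying episode ([find_qualifying_episodes()]) of some
#'    registry molecule starting within `[study_start, inclusion_end]`;
#'    the inclusion date is the earliest such episode start over all
#'    molecules (otherwise exclusion `no_triple`);
#' 2. age at inclusion at least `min_age` (otherwise `under_18`);
#' 3. continuous insurance coverage over the `lookback_days` before inclusion
#'    (otherwise `coverage_gap`);
#' 4. follow-up of at least `min_followup_days` from inclusion to the
#'    follow-up end of [determine_followup_end()] (otherwise
#'    `short_followup`).
#'
#' Every input patient lands in exactly one of the two outputs.
#'
#' @param claims An `ap_claims` object.
#' @param registry Registry tibble from [ap_registry()].
#' @param config An [study_config()] list.
#' @return A list with `cohort` (tibble: `patient_id`, `inclusion_date`,
#'   `qualifying_molecules` list-column, `age_at_inclusion`, `followup_end`,
#'   `end_reason`) and `exclusions` (tibble: `patient_id`, `reason`).
#' @export
select_cohort <- function(claims, registry = ap_registry(),
                          config = study_config()) {
  stopifnot(inherits(claims, "ap_claims"))
  patients <- claims$patients
  ap_disp <- claims$dispensings |>
    filter(is_antipsychotic(.data$molecule, registry))
  disp_by_patient <- split(ap_disp, ap_disp$patient_id)
  cov_by_patient <- split(claims$coverage, claims$coverage$patient_id)

  rows <- purrr::map(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    pid <- p$patient_id
    events <- disp_by_patient[[pid]]
    excl <- function(reason) {
      list(kind = "exclusion", row = tibble(patient_id = pid, reason = reason))
    }
    if (is.null(events) || nrow(events) == 0L) {
      return(excl("no_triple"))
    }
    episodes <- events |>
      group_by(.data$molecule) |>
      summarise(starts = list(find_qualifying_episodes(.data$date))) |>
      mutate(starts = purrr::map(.data$starts, function(s) {
        s[s >= config$study_start & s <= config$inclusion_end]
      })) |>
      filter(lengths(.data$starts) > 0L)
    if (nrow(episodes) == 0L) {
      return(excl("no_triple"))
    }
    inclusion <- min(as.Date(unlist(purrr::map(episodes$starts, min)),
      origin = "1970-01-01"
    ))
    age <- age_at(p$birth_year, p$birth_month, inclusion)
    if (age < config$min_age) {
      return(excl("under_18"))
    }
    cov <- cov_by_patient[[pid]]
    lb_start <- inclusion - config$lookback_days
    if (is.null(cov) || !covers_interval(cov, lb_start, inclusion)) {
      return(excl("coverage_gap"))
    }
    fe <- determine_followup_end(
      events$date, p$death_date, config$study_end, config$followup_gap_days
    )
    if (as.numeric(fe$followup_end - inclusion) < config$min_followup_days) {
      return(excl("short_followup"))
    }
    list(kind = "member", row = tibble(
      patient_id = pid,
      inclusion_date = inclusion,
      qualifying_molecules = list(sort(episodes$molecule)),
      age_at_inclusion = age,
      followup_end = fe$followup_end,
      end_reason = fe$end_reason
    ))
  })

  kinds <- purrr::map_chr(rows, "kind")
  cohort <- purrr::map(rows[kinds == "member"], "row") |> bind_rows()
  exclusions <- purrr::map(rows[kinds == "exclusion"], "row") |> bind_rows()
  if (nrow(cohort) == 0L) {
    cohort <- tibble(
      patient_id = character(), inclusion_date = as.Date(character()),
      qualifying_molecules = list(), age_at_inclusion = integer(),
      followup_end = as.Date(character()), end_reason = character()
    )
  }
  if (nrow(exclusions) == 0L) {
    exclusions <- tibble(patient_id = character(), reason = character())
  }
  list(cohort = cohort, exclusions = exclusions)
}
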