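#' @title Claims tables: schema, validation and IO
#' @description
#' The pipeline consumes a simplified reimbursement-claims schema spread over
#' five CSV files in one directory:
#'
#' * `patients.csv`: `patient_id`, `birth_year`, `birth_month`, `sex`
#'   (`male`/`female`), `death_date` (ISO date or empty), `free_access`
#'   (logical; full coverage of expenses for low-income beneficiaries).
#' * `ald.csv`: `patient_id`, `code`, `start_date` -- chronic-disease (ALD)
#'   registrations granting full coverage for the disease.
#' * `coverage.csv`: `patient_id`, `start_date`, `end_date` -- closed date
#'   intervals of insurance coverage.
#' * `dispensings.csv`: `patient_id`, `date`, `molecule`, `form`
#'   (`oral`/`long_acting`), `units`, `mg_per_unit`, `prescriber_specialty`.
#' * `hospital_diagnoses.csv`: `patient_id`, `date`, `icd10_code`.
#'
#' Dates are ISO-8601 calendar dates. Claims hold month/year of birth only; no
#' birth day is recorded.
#' @name claims_tables
NULL

specialty_levels <- c(
  "general_practitioner", "hospital_practitioner", "psychiatrist",
  "neurologist", "neuropsychiatrist", "child_psychiatrist", "other", "unknown"
)

claims_files <- c(
  patients = "patients.csv", ald = "ald.csv", coverage = "coverage.csv",
  dispensings = "dispensings.csv", diagnoses = "hospital_diagnoses.csv"
)

new_claims <- function(patients, ald, coverage, dispensings, diagnoses,
                       validation = NULL) {
  structure(
    list(
      patients = patients, ald = ald, coverage = coverage,
      dispensings = dispensings, diagnoses = diagnoses,
      validation = validation
    ),
    class = "ap_claims"
  )
}

#' @export
print.ap_claims <- function(x, ...) {
  cat("<ap_claims>\n")
  cat(sprintf(
    "  %d patients, %d dispensings, %d hospital diagnoses\n",
    nrow(x$patients), nrow(x$dispensings), nrow(x$diagnoses)
  ))
  cat(sprintf(
    "  %d ALD records, %d coverage spells\n",
    nrow(x$ald), nrow(x$coverage)
  ))
  if (!is.null(x$validation) && nrow(x$validation$rejected) > 0L) {
    cat(sprintf("  %d rejected rows (see $validation)\n", nrow(x$validation$rejected)))
  }
  invisible(x)
}

reject_log <- function() {
  tibble(table = character(), row = integer(), reason = character())
}

read_csv_chr <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  )
}

parse_date_col <- function(x) as.Date(x, format = "%Y-%m-%d")

parse_int_col <- function(x) suppressWarnings(as.integer(x))

parse_num_col <- function(x) suppressWarnings(as.numeric(x))

parse_lgl_col <- function(x) {
  out <- rep(NA, length(x))
  out[toupper(x) %in% c("TRUE", "T", "1")] <- TRUE
  out[toupper(x) %in% c("FALSE", "F", "0")] <- FALSE
  out
}

#' Read and validate the claims tables
#'
#' Reads the five CSV tables (see [claims_tables]) from a directory, parses
#' dates, validates rows, and sorts event tables by patient and date. A
#' missing required column is a hard error naming the column; an invalid row
#' (unparseable date, non-positive units, unknown category, malformed ICD-10
#' code) is rejected and logged with a reason, never silently kept. Unknown
#' prescriber-specialty codes are mapped to `"unknown"` rather than rejected,
#' since the specialty is descriptive, not an eligibility criterion.
#'
#' Coverage spells are normalized per patient: overlapping or touching spells
#' (and administrative micro-gaps of at most `coverage_gap_tolerance_days`
#' days) are merged, so downstream continuity checks reduce to containment in
#' a single spell.
#'
#' @param dir Directory containing the five CSVs.
#' @param coverage_gap_tolerance_days Micro-gap length (days) still treated as
#'   continuous coverage. Default 0, the strict reading.
#' @return An `ap_claims` object: tibbles `patients`, `ald`, `coverage`
#'   (normalized), `dispensings`, `diagnoses`, plus `validation`, a list with
#'   `counts` (rows read/kept per table) and `rejected` (table, row, reason).
#' @export
read_claims_tables <- function(dir, coverage_gap_tolerance_days = 0) {
  paths <- file.path(dir, claims_files)
  names(paths) <- names(claims_files)
  rejected <- reject_log()
  note <- function(tab, rows, reason) {
    if (length(rows) > 0L) {
      rejected <<- bind_rows(rejected, tibble(
        table = tab, row = as.integer(rows), reason = reason
      ))
    }
  }
  counts <- list()

  # patients
  raw <- read_csv_chr(paths["patients"])
  check_columns(raw, c(
    "patient_id", "birth_year", "birth_month", "sex", "death_date",
    "free_access"
  ), "patients.csv")
  counts$patients_read <- nrow(raw)
  patients <- raw |>
    mutate(
      .row = seq_len(nrow(raw)),
      birth_year = parse_int_col(.data$birth_year),
      birth_month = parse_int_col(.data$birth_month),
      sex = tolower(.data$sex),
      death_date = parse_date_col(.data$death_date),
      free_access = parse_lgl_col(.data$free_access)
    )
  bad <- patients$.row[is.na(patients$birth_year) |
    is.na(patients$birth_month) |
    !(patients$birth_month %in% 1:12)]
  note("patients", bad, "invalid birth year/month")
  bad2 <- patients$.row[!patients$sex %in% c("male", "female")]
  note("patients", bad2, "invalid sex")
  bad3 <- patients$.row[!is.na(raw$death_date) & raw$death_date != "" &
    is.na(patients$death_date)]
  note("patients", bad3, "unparseable death_date")
  bad4 <- patients$.row[is.na(patients$free_access)]
  note("patients", bad4, "invalid free_access")
  patients <- patients |>
    filter(!.data$.row %in% c(bad, bad2, bad3, bad4)) |>
    select(-".row")

  # ald
  raw <- read_csv_chr(paths["ald"])
  check_columns(raw, c("patient_id", "code", "start_date"), "ald.csv")
  counts$ald_read <- nrow(raw)
  ald <- raw |>
    mutate(.row = seq_len(nrow(raw)), start_date = parse_date_col(.data$start_date))
  bad <- ald$.row[is.na(ald$start_date) | is.na(ald$code) | ald$code == ""]
  note("ald", bad, "unparseable date or empty code")
  ald <- ald |>
    filter(!.data$.row %in% bad) |>
    select(-".row") |>
    arrange(.data$patient_id, .data$start_date)

  # coverage
  raw <- read_csv_chr(paths["coverage"])
  check_columns(raw, c("patient_id", "start_date", "end_date"), "coverage.csv")
  counts$coverage_read <- nrow(raw)
  coverage <- raw |>
    mutate(
      .row = seq_len(nrow(raw)),
      start_date = parse_date_col(.data$start_date),
      end_date = parse_date_col(.data$end_date)
    )
  bad <- coverage$.row[is.na(coverage$start_date) | is.na(coverage$end_date)]
  note("coverage", bad, "unparseable date")
  bad2 <- setdiff(
    coverage$.row[!is.na(coverage$start_date) & !is.na(coverage$end_date) &
      coverage$end_date < coverage$start_date],
    bad
  )
  note("coverage", bad2, "end before start")
  coverage <- coverage |>
    filter(!.data$.row %in% c(bad, bad2)) |>
    select(-".row")
  coverage <- normalize_coverage_spells(coverage, coverage_gap_tolerance_days)

  # dispensings
  raw <- read_csv_chr(paths["dispensings"])
  check_columns(raw, c(
    "patient_id", "date", "molecule", "form", "units", "mg_per_unit",
    "prescriber_specialty"
  ), "dispensings.csv")
  counts$dispensings_read <- nrow(raw)
  dispensings <- raw |>
    mutate(
      .row = seq_len(nrow(raw)),
      date = parse_date_col(.data$date),
      molecule = tolower(trimws(.data$molecule)),
      form = tolower(.data$form),
      units = parse_int_col(.data$units),
      mg_per_unit = parse_num_col(.data$mg_per_unit),
      prescriber_specialty = ifelse(
        tolower(.data$prescriber_specialty) %in% specialty_levels,
        tolower(.data$prescriber_specialty), "unknown"
      )
    )
  bad <- dispensings$.row[is.na(dispensings$date)]
  note("dispensings", bad, "unparseable date")
  bad2 <- dispensings$.row[is.na(dispensings$units) | dispensings$units < 1L]
  note("dispensings", setdiff(bad2, bad), "nonpositive units")
  bad3 <- dispensings$.row[is.na(dispensings$mg_per_unit) |
    dispensings$mg_per_unit <= 0]
  note("dispensings", setdiff(bad3, c(bad, bad2)), "nonpositive mg_per_unit")
  bad4 <- dispensings$.row[!dispensings$form %in% c("oral", "long_acting")]
  note("dispensings", setdiff(bad4, c(bad, bad2, bad3)), "invalid form")
  dispensings <- dispensings |>
    filter(!.data$.row %in% c(bad, bad2, bad3, bad4)) |>
    select(-".row") |>
    arrange(.data$patient_id, .data$date)

  # hospital diagnoses
  raw <- read_csv_chr(paths["diagnoses"])
  check_columns(raw, c("patient_id", "date", "icd10_code"), "hospital_diagnoses.csv")
  counts$diagnoses_read <- nrow(raw)
  diagnoses <- raw |>
    mutate(
      .row = seq_len(nrow(raw)),
      date = parse_date_col(.data$date),
      icd10_code = toupper(trimws(.data$icd10_code))
    )
  bad <- diagnoses$.row[is.na(diagnoses$date)]
  note("diagnoses", bad, "unparseable date")
  bad2 <- diagnoses$.row[!grepl("^[A-Z][0-9]+(\\.[0-9]+)?$", diagnoses$icd10_code)]
  note("diagnoses", setdiff(bad2, bad), "malformed icd10 code")
  diagnoses <- diagnoses |>
    filter(!.data$.row %in% c(bad, bad2)) |>
    select(-".row") |>
    arrange(.data$patient_id, .data$date)

  counts$patients_kept <- nrow(patients)
  counts$dispensings_kept <- nrow(dispensings)
  counts$diagnoses_kept <- nrow(diagnoses)
  new_claims(patients, ald, coverage, dispensings, diagnoses,
    validation = list(counts = counts, rejected = rejected)
  )
}

#' Write the claims tables
#'
#' Serializes an `ap_claims` object (or its component tibbles) to the five
#' CSVs read by [read_claims_tables()], with ISO-8601 dates. Writing then
#' re-reading reproduces the tables field for field.
#'
#' @param claims An `ap_claims` object, e.g. from [simulate_population()].
#' @param out_dir Output directory; created if absent.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_claims_tables <- function(claims, out_dir) {
  stopifnot(inherits(claims, "ap_claims"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory: %s", out_dir))
  }
  paths <- file.path(out_dir, claims_files)
  names(paths) <- names(claims_files)
  readr::write_csv(claims$patients, paths["patients"], progress = FALSE)
  readr::write_csv(claims$ald, paths["ald"], progress = FALSE)
  readr::write_csv(claims$coverage, paths["coverage"], progress = FALSE)
  readr::write_csv(claims$dispensings, paths["dispensings"], progress = FALSE)
  readr::write_csv(claims$diagnoses, paths["diagnoses"], progress = FALSE)
  invisible(paths)
}

#' Normalize coverage spells
#'
#' Sorts each patient's coverage spells and merges spells that overlap, touch,
#' or are separated by an administrative micro-gap of at most
#' `tolerance_days` days. Spells are closed date intervals, so spells ending
#' and restarting on consecutive days are continuous. The result equals the
#' union of the covered day sets (plus bridged micro-gaps).
#'
#' @param coverage Tibble with `patient_id`, `start_date`, `end_date`.
#' @param tolerance_days Maximum bridged gap, in days (default 0: only
#'   overlapping or adjacent spells merge).
#' @return Tibble with the same columns, non-overlapping and sorted.
#' @export
normalize_coverage_spells <- function(coverage, tolerance_days = 0) {
  if (nrow(coverage) == 0L) {
    return(as_tibble(coverage))
  }
  coverage |>
    arrange(.data$patient_id, .data$start_date, .data$end_date) |>
    group_by(.data$patient_id) |>
    group_modify_spells(tolerance_days) |>
    ungroup()
}

group_modify_spells <- function(grouped, tolerance_days) {
  dplyr::group_modify(grouped, function(df, key) {
    start <- as.numeric(df$start_date)
    end <- as.numeric(df$end_date)
    merged_start <- start[1]
    merged_end <- end[1]
    out_s <- numeric(0)
    out_e <- numeric(0)
    if (nrow(df) > 1L) {
      for (i in 2:nrow(df)) {
        if (start[i] <= merged_end + 1 + tolerance_days) {
          merged_end <- max(merged_end, end[i])
        } else {
          out_s <- c(out_s, merged_start)
          out_e <- c(out_e, merged_end)
          merged_start <- start[i]
          merged_end <- end[i]
        }
      }
    }
    out_s <- c(out_s, merged_start)
    out_e <- c(out_e, merged_end)
    tibble(
      start_date = as.Date(out_s, origin = "1970-01-01"),
      end_date = as.Date(out_e, origin = "1970-01-01")
    )
  })
}

# TRUE when the patient's normalized spells cover every day of [from, to].
covers_interval <- function(coverage_patient, from, to) {
  any(coverage_patient$start_date <= from & coverage_patient$end_date >= to)
}
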