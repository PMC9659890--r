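#' @importFrom rlang .data abort %||%
#' @importFrom dplyr arrange bind_rows filter group_by left_join mutate n
#'   rename select summarise ungroup distinct first
#' @importFrom tibble tibble as_tibble
NULL

# Round half away from zero, the convention used by the descriptive tables.
round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

as_iso_date <- function(x, what = "date") {
  if (inherits(x, "Date")) {
    return(x)
  }
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  out
}

# Age in completed years assuming birth on day 15 of the birth month
# (claims hold month/year of birth only; day 15 minimizes the maximum error).
age_at <- function(birth_year, birth_month, date) {
  stopifnot(length(birth_year) == length(birth_month))
  before_birthday <- (lubridate::month(date) < birth_month) |
    (lubridate::month(date) == birth_month & lubridate::mday(date) < 15L)
  as.integer(lubridate::year(date) - birth_year - before_birthday)
}

# Sequential calendar-month index (year*12 + month), so consecutive months
# differ by exactly 1 across year boundaries.
month_index <- function(dates) {
  lubridate::year(dates) * 12L + lubridate::month(dates)
}

stop_missing_column <- function(missing, file) {
  abort(sprintf(
    "missing required column%s %s in %s",
    if (length(missing) > 1L) "s" else "",
    paste(sprintf("'%s'", missing), collapse = ", "), file
  ), class = "apclaims_schema_error")
}

check_columns <- function(df, required, file) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) stop_missing_column(missing, file)
  invisible(df)
}
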