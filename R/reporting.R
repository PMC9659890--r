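#' Descriptive numeric summary
#'
#' The descriptive battery used throughout the reports: n, mean, standard
#' deviation, median, quartiles, minimum and maximum. Missing values are
#' dropped before summarizing and do not count toward n. Quartiles use
#' linear interpolation between order statistics (type 7). The standard
#' deviation is `NA` when n = 1.
#'
#' @param x Numeric vector.
#' @return One-row tibble: `n`, `mean`, `sd`, `median`, `q1`, `q3`, `min`,
#'   `max` (all `NA` except `n = 0` for an all-missing input).
#' @export
numeric_summary <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    return(tibble(
      n = 0L, mean = NA_real_, sd = NA_real_, median = NA_real_,
      q1 = NA_real_, q3 = NA_real_, min = NA_real_, max = NA_real_
    ))
  }
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble(
    n = length(x), mean = mean(x),
    sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
    median = q[2], q1 = q[1], q3 = q[3], min = min(x), max = max(x)
  )
}

distribution_table <- function(rows, denominator, rule) {
  rows$percent <- round_half_up(100 * rows$count / denominator, 1)
  structure(rows,
    denominator = denominator, denominator_rule = rule,
    class = c("ap_distribution", class(rows))
  )
}

#' @export
print.ap_distribution <- function(x, ...) {
  cat(sprintf(
    "<distribution over %d patients (%s)>\n",
    attr(x, "denominator"), attr(x, "denominator_rule")
  ))
  NextMethod()
}

#' Distribution of primary antipsychotics
#'
#' Per-molecule patient counts, grouped under their generation class, with
#' percentages over the full cohort. Every registry molecule appears, zero
#' counts included. Counts sum to the cohort size by construction (each
#' patient has exactly one primary antipsychotic).
#'
#' @param assignments Assignment tibble from [assign_pap_cohort()] (or any
#'   tibble with one `pap_molecule` per patient).
#' @param registry Registry tibble.
#' @return An `ap_distribution` tibble: `generation`, `molecule`, `count`,
#'   `percent`; attributes `denominator`, `denominator_rule = "all_cohort"`.
#' @export
pap_distribution <- function(assignments, registry = ap_registry()) {
  classify_generation(assignments$pap_molecule, registry) # errors if unknown
  counts <- assignments |>
    dplyr::count(.data$pap_molecule, name = "count") |>
    rename(molecule = "pap_molecule")
  rows <- registry |>
    select("molecule", "generation") |>
    left_join(counts, by = "molecule") |>
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count)) |>
    arrange(
      factor(.data$generation, levels = c("FGAP", "SGAP", "OTHER")),
      dplyr::desc(.data$count), .data$molecule
    )
  distribution_table(rows, nrow(assignments), "all_cohort")
}

#' First- vs second-generation split and ratio
#'
#' Counts of patients whose primary antipsychotic is first- (FGAP) or
#' second-generation (SGAP). `OTHER`-class primaries (cyamemazine,
#' levomepromazine) are excluded from both the counts and the percentage
#' denominator, since their indications are not antipsychotic. The
#' SGAP/FGAP ratio summarizes prescribing modernity; it is reported
#' unrounded together with its constituent counts, and is `NA` when the
#' FGAP count is zero.
#'
#' @inheritParams pap_distribution
#' @return List: `fgap_count`, `sgap_count`, `ratio` (sgap/fgap),
#'   `fgap_percent`, `sgap_percent` (1-decimal percents of the non-OTHER
#'   total), `denominator` (the non-OTHER total).
#' @export
generation_split <- function(assignments, registry = ap_registry()) {
  gen <- classify_generation(assignments$pap_molecule, registry)
  fgap <- sum(gen == "FGAP")
  sgap <- sum(gen == "SGAP")
  denom <- fgap + sgap
  list(
    fgap_count = fgap, sgap_count = sgap,
    ratio = if (fgap > 0L) sgap / fgap else NA_real_,
    fgap_percent = if (denom > 0L) round_half_up(100 * fgap / denom, 1) else NA_real_,
    sgap_percent = if (denom > 0L) round_half_up(100 * sgap / denom, 1) else NA_real_,
    denominator = denom
  )
}

#' Long-acting primary antipsychotic share
#'
#' A patient counts as having a long-acting primary antipsychotic when at
#' least one dispensing of the primary molecule within its first-to-last
#' span has `form = "long_acting"`. Per-molecule counts and the total, with
#' percentages over the full cohort.
#'
#' @inheritParams pap_distribution
#' @param dispensings Dispensings tibble (`patient_id`, `date`, `molecule`,
#'   `form`).
#' @return An `ap_distribution` tibble: rows per molecule with at least one
#'   long-acting availability plus a `"total"` row.
#' @export
long_acting_share <- function(assignments, dispensings,
                              registry = ap_registry()) {
  la <- dispensings |>
    filter(.data$form == "long_acting") |>
    select("patient_id", "molecule", "date") |>
    dplyr::inner_join(
      assignments |>
        select("patient_id",
          molecule = "pap_molecule",
          first = "pap_first_date", last = "pap_last_date"
        ),
      by = c("patient_id", "molecule")
    ) |>
    filter(.data$date >= .data$first, .data$date <= .data$last) |>
    distinct(.data$patient_id, .data$molecule)
  rows <- la |>
    dplyr::count(.data$molecule, name = "count") |>
    arrange(dplyr::desc(.data$count), .data$molecule)
  rows <- bind_rows(rows, tibble(molecule = "total", count = nrow(la)))
  distribution_table(rows, nrow(assignments), "all_cohort")
}

#' Antipsychotic co-treatment table
#'
#' Bins patients by their number of co-dispensed antipsychotics
#' (0, 1, ..., 5, 6 and more), with percentages over the full cohort, and
#' the share of patients with at least two co-treatments as an attribute
#' `share_ge2` (1-decimal percent).
#'
#' @param exposures Exposure tibble from [compute_exposures()] (needs
#'   `n_co_aps`).
#' @return An `ap_distribution` tibble with rows `0` ... `5`, `6+`.
#' @export
co_treatment_table <- function(exposures) {
  n_co <- exposures$n_co_aps
  bins <- c(as.character(0:5), "6+")
  lab <- ifelse(n_co >= 6L, "6+", as.character(n_co))
  counts <- vapply(bins, function(b) sum(lab == b), integer(1))
  out <- distribution_table(
    tibble(n_co_aps = bins, count = unname(counts)),
    length(n_co), "all_cohort"
  )
  attr(out, "share_ge2") <- round_half_up(100 * sum(n_co >= 2L) / length(n_co), 1)
  out
}

#' Per-molecule numeric summaries
#'
#' Descriptive summaries ([numeric_summary()]) of one metric, by primary
#' antipsychotic. `which = "dwt"` restricts to patients with at least 12
#' months of dispensing of their primary antipsychotic
#' (`eligible_for_dwt_table`), since adherence over the first year is
#' overestimated for patients who stopped or switched earlier. Missing
#' metric values are excluded and do not count toward n; molecules with no
#' contributing patient are omitted.
#'
#' @param cohort Cohort tibble (for `which = "age"`).
#' @param assignments Assignment tibble.
#' @param exposures Exposure tibble from [compute_exposures()].
#' @param which One of `"age"`, `"interval"`, `"units"`,
#'   `"time_on_treatment"`, `"ddd"`, `"dwt"`.
#' @return Tibble with `molecule` and the [numeric_summary()] columns,
#'   sorted by descending n.
#' @export
per_pap_summaries <- function(cohort, assignments, exposures,
                              which = c(
                                "age", "interval", "units",
                                "time_on_treatment", "ddd", "dwt"
                              )) {
  which <- match.arg(which)
  df <- exposures
  if (which == "age") {
    df <- dplyr::inner_join(
      df, cohort |> select("patient_id", "age_at_inclusion"),
      by = "patient_id"
    )
  }
  value <- switch(which,
    age = df$age_at_inclusion,
    interval = df$mean_interval_days,
    units = as.numeric(df$units_first_year),
    time_on_treatment = df$time_on_treatment_months,
    ddd = df$ddd_mg_per_day,
    dwt = df$pct_dwt
  )
  df$.value <- value
  if (which == "dwt") df <- df |> filter(.data$eligible_for_dwt_table)
  df |>
    filter(!is.na(.data$.value)) |>
    group_by(molecule = .data$pap_molecule) |>
    dplyr::group_modify(~ numeric_summary(.x$.value)) |>
    ungroup() |>
    arrange(dplyr::desc(.data$n), .data$molecule)
}

#' Build the full descriptive report
#'
#' Assembles the study's descriptive outputs: the primary-antipsychotic
#' distribution with generation classes, the generation split and SGAP/FGAP
#' ratio, the long-acting share, the co-treatment bins, per-molecule
#' summaries of use (age, inter-dispensing interval, first-year units, time
#' on treatment), dispensed-daily-dose summaries, and the adherence (%DwT)
#' summaries restricted to patients with at least 12 months of dispensing.
#' Optionally writes everything to CSV/JSON files.
#'
#' @param cohort,assignments,exposures Pipeline outputs.
#' @param registry Registry tibble.
#' @param dispensings Dispensings tibble (for the long-acting share);
#'   optional.
#' @param out_dir If non-`NULL`, write `pap_distribution.csv`, `use_*.csv`,
#'   `ddd_summary.csv`, `dwt_summary.csv`, `co_treatment.csv`,
#'   `long_acting.csv` and `summary.json` there.
#' @return A list with elements `pap_distribution`, `generation_split`,
#'   `long_acting` (`NULL` without `dispensings`), `co_treatment`,
#'   `use_summaries` (list by metric), `ddd_summary`, `dwt_summary`,
#'   `summary` (cohort size, ratio and shares).
#' @export
build_report <- function(cohort, assignments, exposures,
                         registry = ap_registry(), dispensings = NULL,
                         out_dir = NULL) {
  dist <- pap_distribution(assignments, registry)
  split <- generation_split(assignments, registry)
  la <- if (!is.null(dispensings)) {
    long_acting_share(assignments, dispensings, registry)
  }
  co <- co_treatment_table(exposures)
  use <- purrr::map(
    rlang::set_names(c("age", "interval", "units", "time_on_treatment")),
    ~ per_pap_summaries(cohort, assignments, exposures, .x)
  )
  ddd <- per_pap_summaries(cohort, assignments, exposures, "ddd")
  dwt <- per_pap_summaries(cohort, assignments, exposures, "dwt")
  summary <- list(
    n_cohort = nrow(assignments),
    fgap_count = split$fgap_count, sgap_count = split$sgap_count,
    sgap_fgap_ratio = split$ratio,
    fgap_percent = split$fgap_percent, sgap_percent = split$sgap_percent,
    long_acting_count = if (!is.null(la)) la$count[la$molecule == "total"],
    long_acting_percent = if (!is.null(la)) la$percent[la$molecule == "total"],
    co_ap_zero_percent = co$percent[co$n_co_aps == "0"],
    co_ap_ge2_percent = attr(co, "share_ge2"),
    n_dwt_eligible = sum(exposures$eligible_for_dwt_table)
  )
  out <- list(
    pap_distribution = dist, generation_split = split, long_acting = la,
    co_treatment = co, use_summaries = use, ddd_summary = ddd,
    dwt_summary = dwt, summary = summary
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(dist, file.path(out_dir, "pap_distribution.csv"))
    for (nm in names(use)) {
      readr::write_csv(use[[nm]], file.path(out_dir, paste0("use_", nm, ".csv")))
    }
    readr::write_csv(ddd, file.path(out_dir, "ddd_summary.csv"))
    readr::write_csv(dwt, file.path(out_dir, "dwt_summary.csv"))
    readr::write_csv(co, file.path(out_dir, "co_treatment.csv"))
    if (!is.null(la)) readr::write_csv(la, file.path(out_dir, "long_acting.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  out
}
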