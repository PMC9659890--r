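#' Run the full utilization pipeline
#'
#' Chains the pipeline stages on a claims object: cohort selection
#' ([select_cohort()]), primary-antipsychotic assignment
#' ([assign_pap_cohort()]), per-patient exposure metrics
#' ([compute_exposures()]) and the descriptive report ([build_report()]).
#'
#' @param claims An `ap_claims` object, from [read_claims_tables()] or
#'   [simulate_population()].
#' @param registry Registry tibble.
#' @param config An [study_config()].
#' @param report Build the descriptive report (default `TRUE`).
#' @param out_dir Optional directory for the report files.
#' @return A list: `cohort`, `exclusions`, `assignments`, `exposures`,
#'   `report` (`NULL` when `report = FALSE`).
#' @examples
#' claims <- simulate_population(simulation_config(n_patients = 40, seed = 7))
#' res <- run_ap_pipeline(claims)
#' res$report$summary$n_cohort
#' @export
run_ap_pipeline <- function(claims, registry = ap_registry(),
                            config = study_config(), report = TRUE,
                            out_dir = NULL) {
  sel <- select_cohort(claims, registry, config)
  assignments <- assign_pap_cohort(claims, sel$cohort, registry)
  exposures <- compute_exposures(claims, sel$cohort, assignments, registry)
  rep <- NULL
  if (report && nrow(assignments) > 0L) {
    rep <- build_report(
      sel$cohort, assignments, exposures, registry,
      dispensings = claims$dispensings, out_dir = out_dir
    )
  }
  list(
    cohort = sel$cohort, exclusions = sel$exclusions,
    assignments = assignments, exposures = exposures, report = rep
  )
}
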