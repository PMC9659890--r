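#' Antipsychotic molecule registry
#'
#' Loads the canonical registry of antipsychotic molecules used throughout the
#' pipeline. Each molecule carries its generation class -- `FGAP` (first
#' generation), `SGAP` (second generation) or `OTHER` -- and whether a
#' long-acting injectable (LAI) form is marketed. The packaged default
#' reproduces the French taxonomy used in national drug-utilization work:
#' 20 first-generation and 6 second-generation molecules, with amisulpride
#' classified as first-generation (the French convention, although it is often
#' called atypical elsewhere), and cyamemazine and levomepromazine set apart
#' as `OTHER` because their French indications target anxiety and
#' aggressiveness rather than psychosis. Paliperidone is marketed only as a
#' long-acting form.
#'
#' National formularies differ, so a user-supplied CSV with the same columns
#' (`molecule`, `generation`, `long_acting_available`, optionally
#' `long_acting_only`) may be passed instead of the packaged default.
#'
#' @param path Path to a registry CSV. `NULL` (default) loads the packaged
#'   registry.
#' @return A tibble with columns `molecule` (canonical lower-case name),
#'   `generation` (factor-like character: `"FGAP"`, `"SGAP"`, `"OTHER"`),
#'   `long_acting_available` and `long_acting_only` (logical).
#' @examples
#' reg <- ap_registry()
#' table(reg$generation)
#' @export
ap_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "antipsychotics_registry.csv",
    package = "apclaims", mustWork = TRUE
  )
  reg <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(reg, c("molecule", "generation", "long_acting_available"), path)
  if (!"long_acting_only" %in% names(reg)) reg$long_acting_only <- FALSE
  reg <- reg |>
    mutate(
      molecule = tolower(trimws(.data$molecule)),
      generation = toupper(.data$generation),
      long_acting_available = as.logical(.data$long_acting_available),
      long_acting_only = as.logical(.data$long_acting_only)
    )
  bad <- setdiff(unique(reg$generation), c("FGAP", "SGAP", "OTHER"))
  if (length(bad) > 0L) {
    abort(sprintf("unknown generation class(es): %s", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(reg$molecule)) abort("duplicated molecules in registry")
  reg
}

registry_lookup <- function(molecule, registry) {
  mol <- tolower(trimws(molecule))
  idx <- match(mol, registry$molecule)
  if (anyNA(idx)) {
    abort(
      sprintf(
        "not an antipsychotic in the registry: %s",
        paste(unique(mol[is.na(idx)]), collapse = ", ")
      ),
      class = "apclaims_not_antipsychotic"
    )
  }
  idx
}

#' Generation class of an antipsychotic molecule
#'
#' Case-insensitive lookup of the generation class (`FGAP`, `SGAP`, `OTHER`).
#' Unknown molecules raise an error of class `apclaims_not_antipsychotic`;
#' there is never a silent default.
#'
#' @param molecule Character vector of molecule names.
#' @param registry Registry tibble from [ap_registry()].
#' @return Character vector of classes, one per input molecule.
#' @examples
#' classify_generation(c("risperidone", "cyamemazine"))
#' @export
classify_generation <- function(molecule, registry = ap_registry()) {
  registry$generation[registry_lookup(molecule, registry)]
}

#' Is a molecule demoted in primary-antipsychotic assignment?
#'
#' Cyamemazine and levomepromazine are dispensed in France mainly against
#' anxiety and aggressiveness, not psychosis, so they become a patient's
#' primary antipsychotic only when no other molecule qualifies. With the
#' packaged registry these are exactly the `OTHER`-generation molecules, and
#' the `OTHER` class is what this predicate tests, so that user-supplied
#' registries keep a consistent rule.
#'
#' @inheritParams classify_generation
#' @return Logical vector.
#' @examples
#' is_excluded_from_pap_priority(c("cyamemazine", "olanzapine"))
#' @export
is_excluded_from_pap_priority <- function(molecule, registry = ap_registry()) {
  classify_generation(molecule, registry) == "OTHER"
}

#' Test membership in the antipsychotic registry
#'
#' @inheritParams classify_generation
#' @return Logical vector; `TRUE` when the molecule is a registered
#'   antipsychotic. Never errors.
#' @export
is_antipsychotic <- function(molecule, registry = ap_registry()) {
  tolower(trimws(molecule)) %in% registry$molecule
}
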