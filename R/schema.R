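#' Privacy-role registries for OMOP CDM columns
#'
#' A schema registry maps OMOP CDM (table, column) pairs to privacy roles:
#' personal health identifiers (PHIs, drawn from the 18 HIPAA identifier
#' categories), demographic quasi-identifiers (QIs), clinical QIs, or plain
#' analysis variables. Each variable additionally carries the kind of value it
#' holds and the safe-harbor masking rule that applies to it: dates are
#' generalised to year only, all other PHIs are fully suppressed, and QIs are
#' left untouched.
#'
#' Two built-in profiles are available through [load_registry()]:
#' \describe{
#'   \item{`"synpuf5pct"`}{the 16 PHIs and 12 QIs present (non-null) in the
#'     SynPUF 5% OMOP CDM v5.2.2 release, hard-coded.}
#'   \item{`"omop_full"`}{a 45-PHI / 17-QI map over the full CDM v5.2 schema,
#'     shipped as an editable YAML reconstruction
#'     (`inst/extdata/omop_full_registry.yaml`); the exact published variable
#'     list is not public, so identities beyond the SynPUF subset are
#'     best-effort.}
#' }
#'
#' @name schema_registry
NULL

VALID_ROLES <- c("PHI", "QI_demographic", "QI_clinical", "other")
VALID_KINDS <- c("date", "code", "geography", "identifier", "year")
VALID_RULES <- c("year_only", "suppress", "none")

#' Construct a variable specification
#'
#' @param table CDM table name.
#' @param column CDM column name.
#' @param role One of `"PHI"`, `"QI_demographic"`, `"QI_clinical"`, `"other"`.
#' @param value_kind One of `"date"`, `"code"`, `"geography"`, `"identifier"`,
#'   `"year"`.
#' @param mask_rule Safe-harbor masking rule: `"year_only"`, `"suppress"` or
#'   `"none"`. Defaults to the rule implied by the role and value kind
#'   (date PHIs are year-generalised, other PHIs suppressed, everything else
#'   untouched).
#' @return A one-row `data.table` with class `variable_spec`.
#' @export
variable_spec <- function(table, column, role,
                          value_kind = "code",
                          mask_rule = NULL) {
  role <- match.arg(role, VALID_ROLES)
  value_kind <- match.arg(value_kind, VALID_KINDS)
  if (is.null(mask_rule)) {
    mask_rule <- if (role == "PHI") {
      if (value_kind == "date") "year_only" else "suppress"
    } else "none"
  }
  mask_rule <- match.arg(mask_rule, VALID_RULES)
  if (role == "PHI" && !mask_rule %in% c("year_only", "suppress"))
    stop_config("PHI %s.%s must be masked (year_only or suppress)", table, column)
  if (role != "PHI" && mask_rule != "none")
    stop_config("non-PHI %s.%s must have mask_rule 'none'", table, column)
  if (role == "PHI" && xor(value_kind == "date", mask_rule == "year_only"))
    stop_config("PHI %s.%s: year_only masking applies to dates, exactly", table, column)
  out <- data.table(
    table_name = normalize_name(table),
    column_name = normalize_name(column),
    role = role, value_kind = value_kind, mask_rule = mask_rule
  )
  setattr(out, "class", c("variable_spec", class(out)))
  out[]
}

new_registry <- function(profile_name, cdm_version, variables) {
  variables <- rbindlist(lapply(variables, as.data.table))
  if (nrow(variables)) {
    dup <- variables[duplicated(variables[, .(table_name, column_name)])]
    if (nrow(dup))
      stop_config("duplicate registry entries: %s",
                  paste(dup$table_name, dup$column_name, sep = ".", collapse = ", "))
  } else {
    variables <- data.table(table_name = character(), column_name = character(),
                            role = character(), value_kind = character(),
                            mask_rule = character())
  }
  structure(
    list(profile_name = profile_name, cdm_version = cdm_version,
         variables = variables),
    class = "schema_registry"
  )
}

# The SynPUF 5% profile: 16 PHIs and 12 QIs present without nulls in the
# v5.2.2 release. Dates and geographic codes are fixed as PHIs (HIPAA
# priority rule); State survives as a demographic QI.
synpuf5pct_registry <- function() {
  v <- list(
    variable_spec("person", "month_of_birth", "PHI", "code"),
    variable_spec("person", "day_of_birth", "PHI", "code"),
    variable_spec("death", "death_date", "PHI", "date"),
    variable_spec("device_exposure", "device_exposure_start_date", "PHI", "date"),
    variable_spec("device_exposure", "device_exposure_end_date", "PHI", "date"),
    variable_spec("drug_exposure", "drug_exposure_start_date", "PHI", "date"),
    variable_spec("drug_exposure", "drug_exposure_end_date", "PHI", "date"),
    variable_spec("location", "county", "PHI", "geography"),
    variable_spec("measurement", "measurement_date", "PHI", "date"),
    variable_spec("observation", "observation_date", "PHI", "date"),
    variable_spec("procedure_occurrence", "procedure_date", "PHI", "date"),
    variable_spec("visit_occurrence", "visit_start_date", "PHI", "date"),
    variable_spec("visit_occurrence", "visit_end_date", "PHI", "date"),
    variable_spec("condition_occurrence", "condition_start_date", "PHI", "date"),
    variable_spec("condition_occurrence", "condition_end_date", "PHI", "date"),
    variable_spec("provider", "npi", "PHI", "identifier"),

    variable_spec("person", "year_of_birth", "QI_demographic", "year"),
    variable_spec("person", "gender_concept_id", "QI_demographic", "code"),
    variable_spec("person", "race_concept_id", "QI_demographic", "code"),
    variable_spec("person", "ethnicity_concept_id", "QI_demographic", "code"),
    variable_spec("location", "state", "QI_demographic", "code"),

    variable_spec("device_exposure", "device_concept_id", "QI_clinical", "code"),
    variable_spec("drug_exposure", "drug_concept_id", "QI_clinical", "code"),
    variable_spec("measurement", "measurement_concept_id", "QI_clinical", "code"),
    variable_spec("observation", "observation_concept_id", "QI_clinical", "code"),
    variable_spec("procedure_occurrence", "procedure_concept_id", "QI_clinical", "code"),
    variable_spec("condition_occurrence", "condition_concept_id", "QI_clinical", "code"),
    variable_spec("care_site", "place_of_service_concept_id", "QI_clinical", "code")
  )
  new_registry("synpuf5pct", "5.2.2", v)
}

#' Load a privacy-role registry
#'
#' @param profile A built-in profile name (`"synpuf5pct"` or `"omop_full"`) or
#'   the path of a registry YAML file (keys `profile_name`, `cdm_version`,
#'   `variables[]` with `table`, `column`, `role`, `value_kind`, `mask_rule`).
#' @return A `schema_registry` object.
#' @examples
#' reg <- load_registry("synpuf5pct")
#' registry_counts(reg)
#' @seealso [classify_variable()], [hipaa_map_report()], [write_registry()]
#' @export
load_registry <- function(profile = "synpuf5pct") {
  if (identical(profile, "synpuf5pct")) return(synpuf5pct_registry())
  if (identical(profile, "omop_full")) {
    path <- system.file("extdata", "omop_full_registry.yaml", package = "cdmprivacy")
    return(read_registry(path))
  }
  if (file.exists(profile)) return(read_registry(profile))
  stop_config("unknown registry profile '%s' (built-ins: synpuf5pct, omop_full)",
              profile)
}

#' Read a registry from YAML
#'
#' @param path Path to a registry YAML document.
#' @return A `schema_registry`.
#' @export
read_registry <- function(path) {
  doc <- yaml::read_yaml(path)
  vars <- lapply(doc$variables, function(e) {
    variable_spec(e$table, e$column, e$role, e$value_kind %||% "code",
                  e$mask_rule)
  })
  new_registry(doc$profile_name %||% basename(path),
               doc$cdm_version %||% "5.x", vars)
}

#' Write a registry to YAML
#'
#' A registry written with `write_registry()` and reloaded with
#' [read_registry()] is identical to the original.
#'
#' @param registry A `schema_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "schema_registry"))
  doc <- list(
    profile_name = registry$profile_name,
    cdm_version = registry$cdm_version,
    variables = lapply(seq_len(nrow(registry$variables)), function(i) {
      r <- registry$variables[i]
      list(table = r$table_name, column = r$column_name, role = r$role,
           value_kind = r$value_kind, mask_rule = r$mask_rule)
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Count PHIs and QIs in a registry
#'
#' @param registry A `schema_registry`.
#' @return Named integer vector with elements `phi`, `qi_demographic`,
#'   `qi_clinical`, `qi` (both QI roles) and `total`.
#' @export
registry_counts <- function(registry) {
  tab <- registry$variables[, table(factor(role, levels = VALID_ROLES))]
  c(phi = unname(tab["PHI"]),
    qi_demographic = unname(tab["QI_demographic"]),
    qi_clinical = unname(tab["QI_clinical"]),
    qi = unname(tab["QI_demographic"] + tab["QI_clinical"]),
    total = nrow(registry$variables))
}

#' Look up the privacy role of a CDM column
#'
#' Matching is case-insensitive on normalised snake_case names. Columns not
#' listed in the registry (surrogate keys, ancillary fields) come back with
#' role `"other"` and no masking, by contract.
#'
#' @param registry A `schema_registry`.
#' @param table CDM table name.
#' @param column CDM column name.
#' @return A one-row `variable_spec`.
#' @examples
#' reg <- load_registry("synpuf5pct")
#' classify_variable(reg, "death", "death_date")$role
#' classify_variable(reg, "person", "person_id")$role
#' @export
classify_variable <- function(registry, table, column) {
  tb <- normalize_name(table); col <- normalize_name(column)
  hit <- registry$variables[table_name == tb & column_name == col]
  if (nrow(hit) == 1L) {
    setattr(hit, "class", c("variable_spec", class(hit)))
    return(hit[])
  }
  out <- data.table(table_name = tb, column_name = col, role = "other",
                    value_kind = "identifier", mask_rule = "none")
  setattr(out, "class", c("variable_spec", class(out)))
  out[]
}

#' Tabulate the HIPAA-to-CDM mapping
#'
#' Renders the registry as one row per variable, grouped by table, in the
#' layout used to report which CDM columns fall under which privacy role.
#'
#' @param registry A `schema_registry`.
#' @return A `data.table` with columns `table_name`, `column_name`, `role`,
#'   `value_kind`, `mask_rule`; one row per registry variable.
#' @export
hipaa_map_report <- function(registry) {
  stopifnot(inherits(registry, "schema_registry"))
  out <- copy(registry$variables)
  setorder(out, table_name, role, column_name)
  out[]
}

#' @export
print.schema_registry <- function(x, ...) {
  cnt <- registry_counts(x)
  cat(sprintf("<schema_registry> profile '%s' (CDM %s): %d PHIs, %d QIs (%d demographic, %d clinical), %d variables\n",
              x$profile_name, x$cdm_version, cnt["phi"], cnt["qi"],
              cnt["qi_demographic"], cnt["qi_clinical"], cnt["total"]))
  invisible(x)
}

# Registry rows for the five common demographic QIs used in every analysis
# dataset: year of birth, gender, race, ethnicity, state.
common_demographics <- function(registry) {
  registry$variables[role == "QI_demographic" &
                       column_name %in% c("year_of_birth", "gender_concept_id",
                                          "race_concept_id", "ethnicity_concept_id",
                                          "state")]
}
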