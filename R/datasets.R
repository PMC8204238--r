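#' Analysis datasets
#'
#' An analysis dataset is a flat table over a declared set of privacy-relevant
#' columns: either a per-PHI "limited" data set (one PHI plus the five common
#' demographic QIs) or a clinical-scenario data set (a driving event table
#' joined to demographics and common PHIs). Surrogate keys (person_id, visit
#' ids, row ids) are never analysis columns -- with them every record would be
#' trivially unique and equivalence-class structure would be meaningless.
#'
#' @name analysis_dataset
NULL

new_analysis_dataset <- function(name, data, columns, n_dropped = 0L,
                                 policy = "limited") {
  key_like <- grep("(^|_)(person_id|row_id)$|_occurrence_id$|_exposure_id$",
                   names(data), value = TRUE)
  if (length(key_like))
    stop_config("surrogate keys may not be analysis columns: %s",
                paste(key_like, collapse = ", "))
  structure(
    list(name = name, data = data, columns = columns,
         n_records = nrow(data), n_dropped = as.integer(n_dropped),
         policy = policy),
    class = "analysis_dataset"
  )
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat(sprintf("<analysis_dataset> '%s' (%s policy): %d records x %d columns (%d null rows dropped)\n",
              x$name, x$policy, x$n_records, ncol(x$data), x$n_dropped))
  cat("  columns:", paste(names(x$data), collapse = ", "), "\n")
  invisible(x)
}

# Pull columns onto a driving table without row duplication: every join is
# many-to-one via match(), so output rows correspond 1:1 to driving rows.
join_columns <- function(cdm, base, wanted) {
  out <- data.table(.rows = seq_len(nrow(base)))
  person <- cdm$person
  pidx <- if ("person_id" %in% names(base))
    match(base$person_id, person$person_id) else rep(NA_integer_, nrow(base))

  vidx <- NULL
  visit_index <- function() {
    if (is.null(vidx)) {
      if (!"visit_occurrence_id" %in% names(base))
        stop_config("join key visit_occurrence_id absent from driving table")
      if (is.null(cdm$visit_occurrence))
        stop_config("visit_occurrence table missing from CDM")
      vidx <<- match(base$visit_occurrence_id,
                     cdm$visit_occurrence$visit_occurrence_id)
    }
    vidx
  }

  for (col in wanted) {
    value <- if (col %in% names(base)) {
      base[[col]]
    } else if (col %in% names(person)) {
      person[[col]][pidx]
    } else if (col %in% c("state", "county")) {
      if (is.null(cdm$location)) stop_config("location table missing from CDM")
      lidx <- match(person$location_id[pidx], cdm$location$location_id)
      cdm$location[[col]][lidx]
    } else if (col %in% c("visit_start_date", "visit_end_date")) {
      cdm$visit_occurrence[[col]][visit_index()]
    } else if (col == "npi") {
      if (is.null(cdm$provider)) stop_config("provider table missing from CDM")
      prov_id <- if ("provider_id" %in% names(base)) base$provider_id
                 else cdm$visit_occurrence$provider_id[visit_index()]
      cdm$provider$npi[match(prov_id, cdm$provider$provider_id)]
    } else if (col == "place_of_service_concept_id") {
      if (is.null(cdm$care_site)) stop_config("care_site table missing from CDM")
      cs_id <- if ("care_site_id" %in% names(base)) base$care_site_id
               else cdm$visit_occurrence$care_site_id[visit_index()]
      cdm$care_site$place_of_service_concept_id[match(cs_id, cdm$care_site$care_site_id)]
    } else if (col == "death_date") {
      if (is.null(cdm$death)) stop_config("death table missing from CDM")
      cdm$death$death_date[match(base$person_id, cdm$death$person_id)]
    } else {
      stop_config("cannot resolve analysis column '%s' from the CDM", col)
    }
    out[[col]] <- value
  }
  out[, .rows := NULL]
  out[]
}

# Driving table for a PHI limited data set. Person-level PHIs (birth fields,
# county) are driven by person; NPI by the visit table (one record per visit,
# matching the published record totals); otherwise the PHI's own table.
phi_driving_table <- function(spec) {
  if (spec$table_name %in% c("person", "location")) return("person")
  if (spec$column_name == "npi") return("visit_occurrence")
  spec$table_name
}

#' Build the limited data set for one PHI
#'
#' One PHI column merged with the five common demographic QIs
#' (`year_of_birth`, `gender_concept_id`, `race_concept_id`,
#' `ethnicity_concept_id`, `state`): six columns, one row per record of the
#' PHI's driving table. Rows with a missing value in any selected column are
#' dropped and counted in `n_dropped`.
#'
#' @param cdm A `cdm_tableset` (from [generate_cdm()] or [read_cdm()]).
#' @param phi A PHI column name (character) or a `variable_spec` row with
#'   role `"PHI"`.
#' @param registry A `schema_registry`; defaults to the SynPUF profile.
#' @return An `analysis_dataset` named after the PHI column.
#' @examples
#' cdm <- generate_cdm(cdm_presets(seed = 1)$toy)
#' build_phi_dataset(cdm, "death_date")
#' @export
build_phi_dataset <- function(cdm, phi, registry = load_registry("synpuf5pct")) {
  if (is.character(phi)) {
    hit <- registry$variables[role == "PHI" & column_name == normalize_name(phi)]
    if (nrow(hit) != 1L) stop_config("'%s' is not a PHI in profile '%s'",
                                     phi, registry$profile_name)
    phi <- hit
  }
  if (!identical(phi$role, "PHI")) stop_config("variable %s.%s is not a PHI",
                                               phi$table_name, phi$column_name)
  driving <- phi_driving_table(phi)
  base <- cdm[[driving]]
  if (is.null(base))
    stop_config("driving table '%s' for PHI '%s' missing from CDM",
                driving, phi$column_name)
  demo <- c("year_of_birth", "gender_concept_id", "race_concept_id",
            "ethnicity_concept_id", "state")
  cols <- c(phi$column_name, demo)
  data <- join_columns(cdm, as.data.table(base), cols)
  keep <- stats::complete.cases(data)
  spec_rows <- rbindlist(lapply(cols, function(cl) {
    tb <- if (cl %in% c(phi$column_name)) phi$table_name
          else if (cl == "state") "location" else "person"
    classify_variable(registry, tb, cl)
  }))
  new_analysis_dataset(phi$column_name, data[keep], spec_rows,
                       n_dropped = sum(!keep))
}

#' Clinical scenario specifications
#'
#' Each scenario is driven by one core event table and contributes its own
#' date PHIs and concept-id QI on top of eleven common variables: the five
#' demographic QIs plus six common PHIs (`month_of_birth`, `day_of_birth`,
#' `county`, `npi`, `visit_start_date`, `visit_end_date`). The death scenario
#' is driven by the visit table left-joined to the death table, so its record
#' count equals the visit count and `death_date` is missing (kept as an
#' explicit missing level, not dropped) for visits of living persons. The
#' medical-history scenario carries `place_of_service_concept_id` as a second
#' QI, bringing the scenario-specific totals to 10 PHIs and 7 QIs.
#'
#' @param name Scenario name.
#' @param driving_table CDM event table the scenario is driven by.
#' @param scenario_phis,scenario_qis Character vectors of scenario-specific
#'   PHI / QI columns.
#' @param optional_join_cols Columns joined from optional tables whose
#'   missing values are kept as an explicit level instead of causing row
#'   drops (used for `death_date` in the death scenario).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(name, driving_table, scenario_phis,
                          scenario_qis = character(),
                          optional_join_cols = character()) {
  structure(
    list(name = name, driving_table = driving_table,
         scenario_phis = scenario_phis, scenario_qis = scenario_qis,
         common_demographics = c("year_of_birth", "gender_concept_id",
                                 "race_concept_id", "ethnicity_concept_id",
                                 "state"),
         common_phis = c("month_of_birth", "day_of_birth", "county", "npi",
                         "visit_start_date", "visit_end_date"),
         optional_join_cols = optional_join_cols),
    class = "scenario_spec"
  )
}

#' The seven default clinical scenarios
#'
#' @return Named list of seven `scenario_spec`s: diagnosis, procedure,
#'   drug_treatment, lab_test, device_treatment, death, medical_history.
#' @export
default_scenarios <- function() {
  list(
    diagnosis = scenario_spec("diagnosis", "condition_occurrence",
                              c("condition_start_date", "condition_end_date"),
                              "condition_concept_id"),
    procedure = scenario_spec("procedure", "procedure_occurrence",
                              "procedure_date", "procedure_concept_id"),
    drug_treatment = scenario_spec("drug_treatment", "drug_exposure",
                                   c("drug_exposure_start_date", "drug_exposure_end_date"),
                                   "drug_concept_id"),
    lab_test = scenario_spec("lab_test", "measurement",
                             "measurement_date", "measurement_concept_id"),
    device_treatment = scenario_spec("device_treatment", "device_exposure",
                                     c("device_exposure_start_date", "device_exposure_end_date"),
                                     "device_concept_id"),
    death = scenario_spec("death", "visit_occurrence",
                          "death_date", character(),
                          optional_join_cols = "death_date"),
    medical_history = scenario_spec("medical_history", "observation",
                                    "observation_date",
                                    c("observation_concept_id",
                                      "place_of_service_concept_id"))
  )
}

#' Build a scenario data set
#'
#' The scenario's driving table is left-joined (many-to-one, no row
#' duplication) to person demographics, location, the visit/provider chain
#' for the common PHIs, and any scenario-specific tables. Column count is
#' 11 common variables plus the scenario's own PHIs and QIs (14 for the
#' diagnosis scenario).
#'
#' @param cdm A `cdm_tableset`.
#' @param scenario A `scenario_spec` or the name of a default scenario.
#' @param registry A `schema_registry`.
#' @return An `analysis_dataset` named after the scenario.
#' @examples
#' cdm <- generate_cdm(cdm_presets(seed = 1)$toy)
#' build_scenario_dataset(cdm, "diagnosis")
#' @export
build_scenario_dataset <- function(cdm, scenario,
                                   registry = load_registry("synpuf5pct")) {
  if (is.character(scenario)) {
    sc <- default_scenarios()[[scenario]]
    if (is.null(sc)) stop_config("unknown scenario '%s'", scenario)
    scenario <- sc
  }
  base <- cdm[[scenario$driving_table]]
  if (is.null(base))
    stop_config("driving table '%s' missing from CDM", scenario$driving_table)
  cols <- c(scenario$scenario_phis, scenario$scenario_qis,
            scenario$common_demographics, scenario$common_phis)
  data <- join_columns(cdm, as.data.table(base), cols)
  required <- setdiff(cols, scenario$optional_join_cols)
  keep <- stats::complete.cases(data[, required, with = FALSE])
  spec_rows <- rbindlist(lapply(cols, function(cl) {
    hit <- registry$variables[column_name == cl]
    if (nrow(hit) >= 1L) hit[1] else classify_variable(registry, "unknown", cl)
  }))
  new_analysis_dataset(scenario$name, data[keep], spec_rows,
                       n_dropped = sum(!keep))
}
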