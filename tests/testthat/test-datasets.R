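test_that("a PHI limited data set is one PHI plus the five common demographics", {
  cdm <- toy_cdm(seed = 1)
  ds <- build_phi_dataset(cdm, "condition_start_date")
  expect_s3_class(ds, "analysis_dataset")
  expect_equal(names(ds$data),
               c("condition_start_date", "year_of_birth", "gender_concept_id",
                 "race_concept_id", "ethnicity_concept_id", "state"))
  expect_equal(ncol(ds$data), 6)
  expect_equal(ds$n_records, nrow(cdm$condition_occurrence))

  # every registry PHI builds a 6-column dataset on the toy CDM
  reg <- load_registry("synpuf5pct")
  for (phi in reg$variables[role == "PHI", column_name]) {
    d <- build_phi_dataset(cdm, phi, reg)
    expect_equal(ncol(d$data), 6, info = phi)
    expect_equal(d$name, phi)
  }
})

test_that("row counts are conserved through the joins", {
  cdm <- micro_cdm()
  vs <- build_phi_dataset(cdm, "visit_start_date")
  expect_equal(vs$n_records, 3)            # one row per visit
  dd <- build_phi_dataset(cdm, "death_date")
  expect_equal(dd$n_records, 1)            # one row per death record
  mb <- build_phi_dataset(cdm, "month_of_birth")
  expect_equal(mb$n_records, 2)            # person-driven
  co <- build_phi_dataset(cdm, "county")
  expect_equal(co$n_records, 2)            # person-driven via location
  np <- build_phi_dataset(cdm, "npi")
  expect_equal(np$n_records, 3)            # visit-driven via provider
  expect_equal(np$data$npi, c("n1", "n2", "n1"))
})

test_that("rows with nulls in selected columns are dropped and counted", {
  cdm <- micro_cdm()
  cdm$person$location_id[1] <- NA_integer_   # person 1 loses their state
  ds <- build_phi_dataset(cdm, "condition_start_date")
  expect_equal(ds$n_records, 2)              # person 1 had 2 condition rows
  expect_equal(ds$n_dropped, 2)
  expect_false(anyNA(ds$data))
})

test_that("surrogate keys never enter analysis columns", {
  cdm <- toy_cdm(seed = 1)
  for (ds in list(build_phi_dataset(cdm, "visit_start_date"),
                  build_scenario_dataset(cdm, "diagnosis"))) {
    expect_false(any(grepl("(person|occurrence|exposure)_id$", names(ds$data))))
  }
  reg <- load_registry("synpuf5pct")
  audit <- vapply(names(build_scenario_dataset(cdm, "diagnosis")$data),
                  function(cl) nrow(reg$variables[column_name == cl]) == 1L,
                  logical(1))
  expect_true(all(audit))                    # every column resolves to a role
})

test_that("the seven default scenarios match their contracts", {
  sc <- default_scenarios()
  expect_setequal(names(sc),
                  c("diagnosis", "procedure", "drug_treatment", "lab_test",
                    "device_treatment", "death", "medical_history"))
  for (s in sc) {
    expect_length(s$common_demographics, 5)
    expect_length(s$common_phis, 6)
    expect_gte(11 + length(s$scenario_phis) + length(s$scenario_qis), 12)
  }
  # scenario-specific assignments total 10 PHIs and 7 QIs
  expect_length(unlist(lapply(sc, `[[`, "scenario_phis")), 10)
  expect_length(unlist(lapply(sc, `[[`, "scenario_qis")), 7)
})

test_that("scenario datasets have the declared shape", {
  cdm <- toy_cdm(seed = 3)
  dg <- build_scenario_dataset(cdm, "diagnosis")
  expect_equal(ncol(dg$data), 14)
  expect_true(all(c("condition_start_date", "condition_end_date",
                    "condition_concept_id") %in% names(dg$data)))
  expect_equal(dg$n_records, nrow(cdm$condition_occurrence))

  # death scenario is visit-driven; missing death dates are kept, not dropped
  de <- build_scenario_dataset(cdm, "death")
  expect_equal(de$n_records, nrow(cdm$visit_occurrence))
  expect_true(anyNA(de$data$death_date))
  expect_equal(ncol(de$data), 12)

  for (nm in names(default_scenarios())) {
    d <- build_scenario_dataset(cdm, nm)
    expect_lte(d$n_records, nrow(cdm[[default_scenarios()[[nm]]$driving_table]]))
  }
})

test_that("an empty event table yields a valid empty dataset", {
  cdm <- micro_cdm()
  cdm$condition_occurrence <- cdm$condition_occurrence[0]
  ds <- build_scenario_dataset(cdm, "diagnosis")
  expect_equal(ds$n_records, 0)
  expect_equal(ncol(ds$data), 14)
})

test_that("missing tables and unknown variables raise clear errors", {
  cdm <- micro_cdm()
  cdm$death <- NULL
  expect_error(build_phi_dataset(cdm, "death_date"), "missing")
  expect_error(build_phi_dataset(micro_cdm(), "not_a_phi"), "not a PHI")
  expect_error(build_scenario_dataset(micro_cdm(), "no_such_scenario"),
               "unknown scenario")
})
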