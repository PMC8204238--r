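test_that("the PHI experiment emits one row per PHI plus an average row", {
  cdm <- toy_cdm(seed = 1)
  rep <- run_phi_experiment(cdm)
  expect_equal(nrow(rep), 17)                       # 16 PHIs + Average
  expect_equal(rep$variable[17], "Average")
  expect_true(all(rep$gap_unique_pct[1:16] >= 0))   # coarsening on every row
  expect_true(all(rep$gap_max_ec[1:16] >= 0))
  expect_equal(rep$gap_unique_pct[17], mean(rep$gap_unique_pct[1:16]))
  # every row is recomputable from its own columns
  expect_equal(rep$limited_unique_pct[1:16],
               100 * rep$limited_unique[1:16] / rep$n_records[1:16])
})

test_that("a missing table becomes an error row, not a failed run", {
  cdm <- toy_cdm(seed = 1)
  cdm$death <- NULL
  rep <- run_phi_experiment(cdm)
  errs <- attr(rep, "errors")
  expect_named(errs, "death_date")
  expect_true(is.na(rep[variable == "death_date", n_records]))
  expect_equal(nrow(rep), 17)
})

test_that("the QI experiment covers the seven scenarios and the k=1..20 export", {
  cdm <- toy_cdm(seed = 2)
  rep <- run_qi_experiment(cdm)
  expect_equal(nrow(rep), 8)                        # 7 scenarios + Average
  expect_setequal(setdiff(rep$scenario, "Average"),
                  names(default_scenarios()))
  # partial mass: percents at 1, 2, 5 cannot exceed 100
  sums <- rep[scenario != "Average",
              limited_pct_1 + limited_pct_2 + limited_pct_5]
  expect_true(all(sums <= 100 + 1e-9))
  expect_true(all(rep[scenario != "Average", gap_pct_1] >= 0))

  dist <- attr(rep, "distribution")
  expect_equal(nrow(dist), 7 * 2 * 20)
  expect_setequal(unique(dist$k), 1:20)
  expect_setequal(unique(dist$policy), c("limited", "safe_harbor"))
})

test_that("the sampling grid marks oversized cells and averages the rest", {
  cdm <- toy_cdm(seed = 3)
  scen <- lapply(default_scenarios()[c("diagnosis", "death")],
                 function(sc) build_scenario_dataset(cdm, sc))
  grid <- suppressMessages(
    run_sampling_experiment(scen, sample_sizes = c(10, 1e6),
                            iterations = 5, seed = 1))
  small <- grid[sample_size == 10]
  expect_setequal(small$dataset, c("diagnosis", "death", "Average"))
  expect_false(any(small$skipped))
  expect_equal(small[dataset == "Average", gap_pct],
               mean(small[dataset != "Average", gap_pct]))
  big <- grid[sample_size == 1e6]
  expect_true(all(big$skipped))
  expect_false("Average" %in% big$dataset)

  grid2 <- suppressMessages(
    run_sampling_experiment(scen, sample_sizes = c(10, 1e6),
                            iterations = 5, seed = 1))
  expect_equal(grid, grid2)                         # deterministic rerun
})

test_that("the pipeline writes recomputable reports end to end", {
  out <- withr::local_tempdir()
  res <- run_privacy_pipeline(list(
    input = list(synthetic = list(
      n_persons = 25,
      events = list(visit_occurrence = list(dist = "poisson", lambda = 3),
                    condition_occurrence = list(dist = "poisson", lambda = 4),
                    procedure_occurrence = list(dist = "poisson", lambda = 3),
                    drug_exposure = list(dist = "poisson", lambda = 2),
                    device_exposure = list(dist = "poisson", lambda = 1),
                    measurement = list(dist = "poisson", lambda = 2),
                    observation = list(dist = "poisson", lambda = 2)),
      vocab_sizes = list(condition_concept_id = 10, procedure_concept_id = 10,
                         drug_concept_id = 5, measurement_concept_id = 5,
                         observation_concept_id = 5, device_concept_id = 3,
                         county = 8, state = 4, npi = 10))),
    sample_sizes = c(5, 10), iterations = 5, seed = 11, out_dir = out))
  for (f in c("phi_experiment.csv", "qi_experiment.csv",
              "sampling_experiment.csv", "cell_size_distribution.csv",
              "manifest.json")) {
    expect_true(file.exists(file.path(out, f)), info = f)
  }
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$seed, 11)
  expect_equal(manifest$datasets$diagnosis$n_records,
               res$qi[scenario == "diagnosis", n_records])
  # written numbers match the in-memory report at presentation rounding
  disk <- data.table::fread(file.path(out, "phi_experiment.csv"))
  expect_equal(disk$gap_unique_pct, round(res$phi$gap_unique_pct, 3))
})

test_that("the CLI driver runs the generate and evaluate subcommands", {
  script <- system.file("scripts", "cdmprivacy", package = "cdmprivacy")
  expect_true(nzchar(script))
  dir <- withr::local_tempdir()
  cdm_dir <- file.path(dir, "cdm"); out_dir <- file.path(dir, "reports")
  s1 <- system2("Rscript", c(script, "generate", "--out", cdm_dir,
                             "--preset", "toy", "--seed", "5"),
                stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(cdm_dir, "person.csv")))
  s2 <- system2("Rscript", c(script, "evaluate", "--input-cdm", cdm_dir,
                             "--out", out_dir, "--seed", "5"),
                stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out_dir, "phi_experiment.csv")))
  rep <- data.table::fread(file.path(out_dir, "phi_experiment.csv"))
  expect_equal(nrow(rep), 17)
})
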