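test_that("generation is deterministic for a fixed config and seed", {
  a <- toy_cdm(seed = 7)
  b <- toy_cdm(seed = 7)
  expect_equal(names(a), names(b))
  for (nm in names(a)) expect_equal(a[[nm]], b[[nm]], info = nm)
  c <- toy_cdm(seed = 8)
  expect_false(identical(a$visit_occurrence, c$visit_occurrence))
})

test_that("structural invariants hold on generated tables", {
  cfg <- synthetic_config(n_persons = 100, death_fraction = 0.1, seed = 7,
                          events = list(visit_occurrence = list(dist = "poisson", lambda = 3)))
  cdm <- generate_cdm(cfg)
  expect_equal(nrow(cdm$person), 100)
  expect_equal(nrow(cdm$death), 10)           # round(100 * 0.1), one row each
  expect_false(anyDuplicated(cdm$death$person_id) > 0)
  expect_true(all(cdm$person$day_of_birth == 1L))
  rng <- cfg$date_range
  for (tb in c("visit_occurrence", "condition_occurrence", "death")) {
    for (col in grep("_date$", names(cdm[[tb]]), value = TRUE)) {
      expect_true(all(cdm[[tb]][[col]] >= rng[1] & cdm[[tb]][[col]] <= rng[2]),
                  info = paste(tb, col))
    }
  }
  # end dates never precede start dates
  expect_true(all(cdm$visit_occurrence$visit_end_date >=
                    cdm$visit_occurrence$visit_start_date))
  # no missing values in generated analysis columns
  for (tb in names(cdm)) expect_false(anyNA(cdm[[tb]]), info = tb)
  # non-constant day of birth when requested
  cdm2 <- generate_cdm(synthetic_config(n_persons = 200, seed = 3,
                                        day_of_birth_constant = FALSE))
  expect_gt(data.table::uniqueN(cdm2$person$day_of_birth), 1)
})

test_that("Poisson event totals land near n * lambda", {
  cfg <- synthetic_config(
    n_persons = 1000, seed = 1,
    events = list(visit_occurrence = list(dist = "poisson", lambda = 12)))
  total <- nrow(generate_cdm(cfg)$visit_occurrence)
  expect_lt(abs(total - 12000), 4 * sqrt(12000))
})

test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(n_persons = 0), "n_persons")
  expect_error(synthetic_config(date_range = c("2010-12-31", "2008-01-01")),
               "inverted")
  expect_error(synthetic_config(death_fraction = 1.5), "death_fraction")
  expect_error(synthetic_config(vocab_sizes = list(state = 0)), "vocab")
})

test_that("presets are valid and match their contracts", {
  p <- cdm_presets(seed = 5)
  expect_setequal(names(p), c("synpuf_like", "toy"))
  for (cfg in p) expect_s3_class(cfg, "synthetic_config")
  expect_equal(format(p$synpuf_like$date_range, "%Y"), c("2008", "2010"))
  expect_lte(p$toy$n_persons, 50)
  expect_true(p$synpuf_like$day_of_birth_constant)
  expect_equal(p$synpuf_like$n_persons, 25200)
  expect_equal(round(p$synpuf_like$n_persons * p$synpuf_like$death_fraction), 1155)
})

test_that("CSV round trip preserves tables and ISO dates", {
  cdm <- toy_cdm(seed = 2)
  dir <- withr::local_tempdir()
  write_cdm(cdm, dir)
  raw <- readLines(file.path(dir, "death.csv"), n = 2)
  expect_match(raw[2], "\\d{4}-\\d{2}-\\d{2}")
  back <- read_cdm(dir)
  expect_setequal(names(back), names(cdm))
  for (nm in names(cdm)) {
    orig <- data.table::as.data.table(cdm[[nm]])
    rt <- back[[nm]][, names(orig), with = FALSE]
    for (col in names(orig)) {
      if (inherits(orig[[col]], "Date")) {
        expect_equal(as.Date(rt[[col]]), as.Date(orig[[col]]))
      } else {
        expect_equal(as.character(rt[[col]]), as.character(orig[[col]]))
      }
    }
  }
})

test_that("single-occurrence death dates stay more unique than multi-occurrence visit dates", {
  # one record per deceased person vs dozens per person: after safe-harbor
  # masking the death-date data set retains more unique records
  wins <- vapply(1:5, function(s) {
    cdm <- generate_cdm(synthetic_config(
      n_persons = 150, death_fraction = 0.3, seed = s,
      events = list(visit_occurrence = list(dist = "poisson", lambda = 30))))
    u <- function(phi) {
      ds <- apply_policy(build_phi_dataset(cdm, phi), "safe_harbor")
      unique_record_percent(equivalence_profile(ds))
    }
    u("death_date") > u("visit_start_date")
  }, logical(1))
  expect_true(all(wins))
})

test_that("wider vocabularies do not decrease expected uniqueness (balls and bins)", {
  mean_unique <- function(k) {
    mean(vapply(1:5, function(s) {
      cfg <- synthetic_config(
        n_persons = 120, seed = s,
        events = list(condition_occurrence = list(dist = "poisson", lambda = 5)),
        vocab_sizes = list(condition_concept_id = k))
      cdm <- generate_cdm(cfg)
      ds <- build_scenario_dataset(cdm, "diagnosis")
      unique_record_percent(equivalence_profile(ds, "condition_concept_id"))
    }, numeric(1)))
  }
  u <- vapply(c(5, 50, 500), mean_unique, numeric(1))
  expect_true(all(diff(u) >= 0))
})
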