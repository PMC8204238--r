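# Shared fixtures and independent oracles.

toy_cdm <- function(seed = 1) {
  generate_cdm(cdm_presets(seed = seed)$toy)
}

# Hand-built micro CDM: 2 persons, 3 visits, known joins.
micro_cdm <- function() {
  structure(list(
    person = data.table::data.table(
      person_id = 1:2, year_of_birth = c(1950L, 1960L),
      month_of_birth = c(3L, 7L), day_of_birth = c(1L, 1L),
      gender_concept_id = c(1L, 2L), race_concept_id = c(1L, 1L),
      ethnicity_concept_id = c(1L, 2L), location_id = c(1L, 2L)),
    location = data.table::data.table(
      location_id = 1:2, county = c("c1", "c2"), state = c("s1", "s2")),
    provider = data.table::data.table(provider_id = 1:2, npi = c("n1", "n2")),
    care_site = data.table::data.table(
      care_site_id = 1:2, place_of_service_concept_id = c(10L, 20L)),
    death = data.table::data.table(
      person_id = 2L, death_date = as.Date("2009-06-15")),
    visit_occurrence = data.table::data.table(
      visit_occurrence_id = 1:3, person_id = c(1L, 1L, 2L),
      visit_start_date = as.Date(c("2008-01-02", "2008-05-05", "2009-02-02")),
      visit_end_date = as.Date(c("2008-01-05", "2008-05-06", "2009-02-02")),
      provider_id = c(1L, 2L, 1L), care_site_id = c(1L, 1L, 2L)),
    condition_occurrence = data.table::data.table(
      condition_occurrence_id = 1:4, person_id = c(1L, 1L, 2L, 2L),
      visit_occurrence_id = c(1L, 2L, 3L, 3L),
      condition_start_date = as.Date(c("2008-01-02", "2008-05-05",
                                       "2009-02-02", "2009-02-03")),
      condition_end_date = as.Date(c("2008-01-09", "2008-05-07",
                                     "2009-02-04", "2009-02-05")),
      condition_concept_id = c(100L, 101L, 100L, 102L))
  ), class = "cdm_tableset")
}

# O(N^2) pairwise-equality oracle for equivalence-class histograms:
# compares every pair of rows column by column, no grouping machinery.
oracle_histogram <- function(df) {
  df <- as.data.frame(df)
  n <- nrow(df)
  eq <- matrix(TRUE, n, n)
  for (col in df) {
    key <- as.character(col)
    key[is.na(key)] <- "\r<NA>"
    eq <- eq & outer(key, key, "==")
  }
  sizes <- rowSums(eq)                     # class size seen from each row
  # c_k = (#rows with size k) / k
  tab <- table(sizes)
  data.table::data.table(size = as.integer(names(tab)),
                         classes = as.numeric(tab) / as.integer(names(tab)))
}

random_table <- function(n, ncol = 3, cards = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cards <- cards %||% sample(2:8, ncol, replace = TRUE)
  out <- lapply(seq_len(ncol), function(j) {
    sample(paste0("v", seq_len(cards[j])), n, replace = TRUE)
  })
  names(out) <- paste0("col", seq_len(ncol))
  data.table::as.data.table(out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

expect_same_histogram <- function(profile, oracle) {
  got <- profile$histogram[order(size)]
  want <- oracle[order(size)]
  expect_equal(got$size, want$size)
  expect_equal(got$classes, want$classes)
}
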