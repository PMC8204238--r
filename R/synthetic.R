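#' Synthetic OMOP CDM generator
#'
#' Generates a set of OMOP-CDM-shaped tables with the statistical structure
#' that the privacy-risk analysis depends on: a fixed 3-year event window,
#' per-person event multiplicity that differs by table (exactly one death date
#' per deceased person versus dozens of visits and conditions), a day of birth
#' already generalised to the constant 1, small-cardinality demographic codes,
#' and configurable distinct-value cardinality (vocabulary size) per coded
#' column. Clinical plausibility is explicitly out of scope; the generator
#' emulates record-linkage structure, not medicine.
#'
#' @name synthetic_cdm
NULL

# Tables that carry per-person clinical events, with their date/code columns.
EVENT_TABLES <- list(
  visit_occurrence = list(id = "visit_occurrence_id",
                          start = "visit_start_date", end = "visit_end_date",
                          concept = NULL),
  condition_occurrence = list(id = "condition_occurrence_id",
                              start = "condition_start_date", end = "condition_end_date",
                              concept = "condition_concept_id"),
  procedure_occurrence = list(id = "procedure_occurrence_id",
                              start = "procedure_date", end = NULL,
                              concept = "procedure_concept_id"),
  drug_exposure = list(id = "drug_exposure_id",
                       start = "drug_exposure_start_date", end = "drug_exposure_end_date",
                       concept = "drug_concept_id"),
  device_exposure = list(id = "device_exposure_id",
                         start = "device_exposure_start_date", end = "device_exposure_end_date",
                         concept = "device_concept_id"),
  measurement = list(id = "measurement_id",
                     start = "measurement_date", end = NULL,
                     concept = "measurement_concept_id"),
  observation = list(id = "observation_id",
                     start = "observation_date", end = NULL,
                     concept = "observation_concept_id")
)

#' Configure the synthetic CDM generator
#'
#' @param n_persons Number of persons (rows of `person`).
#' @param date_range Character or Date vector of length 2: inclusive event
#'   window. All generated event and death dates fall inside it.
#' @param events Named list mapping an event table to its per-person
#'   event-count distribution: `list(dist = "fixed", k = )`,
#'   `list(dist = "poisson", lambda = )`, or
#'   `list(dist = "zip", lambda = , p0 = )` (zero-inflated Poisson). Tables
#'   omitted here fall back to `Poisson(2)`.
#' @param vocab_sizes Named list of distinct-value counts for coded columns
#'   (`gender_concept_id`, `race_concept_id`, `ethnicity_concept_id`, `state`,
#'   `county`, the clinical `*_concept_id`s, `place_of_service_concept_id`,
#'   `npi`). Defaults: gender 2, race 5, ethnicity 2, state 50, county 300,
#'   condition/procedure 1000, drug/measurement/observation 500, device 100,
#'   place of service 20, npi 5000.
#' @param death_fraction Fraction of persons with a death record; the death
#'   table gets exactly `round(n_persons * death_fraction)` rows, one per
#'   deceased person.
#' @param day_of_birth_constant If `TRUE` (default), every `day_of_birth` is 1,
#'   matching a source that was already generalised at that field.
#' @param birth_year_range Integer vector of length 2: uniform range for
#'   `year_of_birth`.
#' @param end_offset_max Event end dates are the start date plus a uniform
#'   0..`end_offset_max` day offset (clamped to the window), so start/end pairs
#'   are correlated as in real data.
#' @param zipf_exponent Skew of the rank-frequency distribution codes are
#'   drawn from (probability of rank r proportional to `r^-zipf_exponent`);
#'   0 gives uniform draws. Real order codes are heavily skewed.
#' @param seed Master seed. Each table draws from a substream derived from the
#'   seed and the table name, so output is reproducible table by table.
#' @return A validated `synthetic_config` list.
#' @seealso [generate_cdm()], [cdm_presets()]
#' @export
synthetic_config <- function(n_persons = 1000,
                             date_range = c("2008-01-01", "2010-12-31"),
                             events = list(),
                             vocab_sizes = list(),
                             death_fraction = 0.05,
                             day_of_birth_constant = TRUE,
                             birth_year_range = c(1909, 1983),
                             end_offset_max = 30,
                             zipf_exponent = 1,
                             seed = 1L) {
  default_events <- list(
    visit_occurrence = list(dist = "poisson", lambda = 48.4),
    condition_occurrence = list(dist = "poisson", lambda = 128.2),
    procedure_occurrence = list(dist = "poisson", lambda = 120.0),
    drug_exposure = list(dist = "poisson", lambda = 6.3),
    device_exposure = list(dist = "poisson", lambda = 1.9),
    measurement = list(dist = "poisson", lambda = 29.4),
    observation = list(dist = "poisson", lambda = 16.7)
  )
  default_vocab <- list(
    gender_concept_id = 2, race_concept_id = 5, ethnicity_concept_id = 2,
    state = 50, county = 300,
    condition_concept_id = 1000, procedure_concept_id = 1000,
    drug_concept_id = 500, measurement_concept_id = 500,
    observation_concept_id = 500, device_concept_id = 100,
    place_of_service_concept_id = 20, npi = 5000
  )
  cfg <- list(
    n_persons = as.integer(n_persons),
    date_range = as.Date(date_range),
    events = utils::modifyList(default_events, events),
    vocab_sizes = utils::modifyList(default_vocab, vocab_sizes),
    death_fraction = death_fraction,
    day_of_birth_constant = isTRUE(day_of_birth_constant),
    birth_year_range = as.integer(birth_year_range),
    end_offset_max = as.integer(end_offset_max),
    zipf_exponent = zipf_exponent,
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (!is_scalar_number(cfg$n_persons) || cfg$n_persons < 1)
    stop_config("n_persons must be >= 1")
  if (length(cfg$date_range) != 2L || anyNA(cfg$date_range))
    stop_config("date_range must be two parseable dates")
  if (cfg$date_range[1] > cfg$date_range[2])
    stop_config("date_range is inverted: %s > %s",
                cfg$date_range[1], cfg$date_range[2])
  if (!is_scalar_number(cfg$death_fraction) ||
      cfg$death_fraction < 0 || cfg$death_fraction > 1)
    stop_config("death_fraction must lie in [0, 1]")
  if (any(unlist(cfg$vocab_sizes) < 1))
    stop_config("all vocab sizes must be >= 1")
  for (tb in names(cfg$events)) {
    e <- cfg$events[[tb]]
    if (!e$dist %in% c("fixed", "poisson", "zip"))
      stop_config("unknown event distribution '%s' for %s", e$dist, tb)
  }
  invisible(cfg)
}

#' Built-in generator presets
#'
#' @return Named list of `synthetic_config` objects:
#' \describe{
#'   \item{`synpuf_like`}{calibrated to the SynPUF 5% study subset: 25,200
#'     persons over 2008--2010, death fraction 1155/25200, per-table Poisson
#'     event rates matching the published per-table record totals, and
#'     `day_of_birth` constant at 1.}
#'   \item{`toy`}{30 persons with small event rates, for unit tests and
#'     examples.}
#' }
#' @param seed Master seed stored in each preset.
#' @export
cdm_presets <- function(seed = 1L) {
  list(
    synpuf_like = synthetic_config(
      n_persons = 25200,
      death_fraction = 1155 / 25200,
      seed = seed
    ),
    toy = synthetic_config(
      n_persons = 30,
      events = list(
        visit_occurrence = list(dist = "poisson", lambda = 4),
        condition_occurrence = list(dist = "poisson", lambda = 6),
        procedure_occurrence = list(dist = "poisson", lambda = 5),
        drug_exposure = list(dist = "poisson", lambda = 2),
        device_exposure = list(dist = "poisson", lambda = 1),
        measurement = list(dist = "poisson", lambda = 3),
        observation = list(dist = "poisson", lambda = 2)
      ),
      vocab_sizes = list(
        condition_concept_id = 20, procedure_concept_id = 20,
        drug_concept_id = 10, measurement_concept_id = 10,
        observation_concept_id = 10, device_concept_id = 5,
        county = 12, state = 6, npi = 15, place_of_service_concept_id = 4
      ),
      death_fraction = 0.2,
      seed = seed
    )
  )
}

# Skewed rank-frequency draw: P(rank r) proportional to r^-s over 1..k.
sample_codes <- function(n, k, s) {
  if (k == 1L) return(rep.int(1L, n))
  w <- (seq_len(k))^(-s)
  sample.int(k, n, replace = TRUE, prob = w / sum(w))
}

sample_dates <- function(n, range) {
  lo <- as.integer(range[1]); hi <- as.integer(range[2])
  as.Date(sample.int(hi - lo + 1L, n, replace = TRUE) + lo - 1L,
          origin = "1970-01-01")
}

draw_event_counts <- function(n, spec) {
  counts <- switch(spec$dist,
    fixed = rep.int(as.integer(spec$k), n),
    poisson = rpois(n, spec$lambda),
    zip = rpois(n, spec$lambda) * (runif(n) >= spec$p0)
  )
  as.integer(counts)
}

#' Generate a synthetic CDM table set
#'
#' Deterministic for a fixed config (including its seed): every table is drawn
#' from a substream keyed on the master seed and the table name, so the same
#' config always yields byte-identical tables and adding one table does not
#' perturb the others. Generated analysis columns contain no missing values.
#'
#' @param config A [synthetic_config()] (or the name of a preset from
#'   [cdm_presets()]).
#' @return A `cdm_tableset`: named list of `data.table`s (`person`, `death`,
#'   `location`, `provider`, `care_site`, plus the seven event tables), with
#'   the config attached as attribute `config`.
#' @examples
#' cdm <- generate_cdm(cdm_presets(seed = 7)$toy)
#' sapply(cdm, nrow)
#' @export
generate_cdm <- function(config) {
  if (is.character(config)) {
    presets <- cdm_presets()
    if (!config %in% names(presets))
      stop_config("unknown preset '%s'", config)
    config <- presets[[config]]
  }
  validate_synthetic_config(config)
  cfg <- config
  n <- cfg$n_persons
  vz <- cfg$vocab_sizes
  s <- cfg$zipf_exponent

  # location: one row per county; states cycle so county determines state
  n_loc <- as.integer(vz$county)
  location <- data.table(
    location_id = seq_len(n_loc),
    county = sprintf("county_%03d", seq_len(n_loc)),
    state = sprintf("state_%02d", ((seq_len(n_loc) - 1L) %% as.integer(vz$state)) + 1L)
  )

  set.seed(substream_seed(cfg$seed, "person"))
  person <- data.table(
    person_id = seq_len(n),
    year_of_birth = sample(seq(cfg$birth_year_range[1], cfg$birth_year_range[2]),
                           n, replace = TRUE),
    month_of_birth = sample.int(12L, n, replace = TRUE),
    day_of_birth = if (cfg$day_of_birth_constant) rep.int(1L, n)
                   else sample.int(28L, n, replace = TRUE),
    gender_concept_id = sample_codes(n, vz$gender_concept_id, s),
    race_concept_id = sample_codes(n, vz$race_concept_id, s),
    ethnicity_concept_id = sample_codes(n, vz$ethnicity_concept_id, s),
    location_id = sample_codes(n, n_loc, s)
  )

  set.seed(substream_seed(cfg$seed, "provider"))
  n_prov <- as.integer(vz$npi)
  provider <- data.table(
    provider_id = seq_len(n_prov),
    npi = sprintf("%010d", sample.int(999999999L, n_prov))
  )

  set.seed(substream_seed(cfg$seed, "care_site"))
  n_cs <- max(10L, as.integer(vz$place_of_service_concept_id))
  care_site <- data.table(
    care_site_id = seq_len(n_cs),
    place_of_service_concept_id = sample_codes(n_cs, vz$place_of_service_concept_id, s)
  )

  set.seed(substream_seed(cfg$seed, "death"))
  n_dead <- as.integer(round(n * cfg$death_fraction))
  death <- data.table(
    person_id = sort(sample.int(n, n_dead)),
    death_date = sample_dates(n_dead, cfg$date_range)
  )

  cdm <- list(person = person, death = death, location = location,
              provider = provider, care_site = care_site)

  # visits first: clinical events link to a visit of the same person
  set.seed(substream_seed(cfg$seed, "visit_occurrence"))
  nv <- draw_event_counts(n, cfg$events$visit_occurrence)
  total_v <- sum(nv)
  visit <- data.table(
    visit_occurrence_id = seq_len(total_v),
    person_id = rep.int(seq_len(n), nv),
    visit_start_date = sample_dates(total_v, cfg$date_range),
    provider_id = sample_codes(total_v, n_prov, s),
    care_site_id = sample_codes(total_v, n_cs, s)
  )
  visit[, visit_end_date := pmin(visit_start_date +
                                   sample.int(cfg$end_offset_max + 1L, total_v, replace = TRUE) - 1L,
                                 cfg$date_range[2])]
  setcolorder(visit, c("visit_occurrence_id", "person_id",
                       "visit_start_date", "visit_end_date",
                       "provider_id", "care_site_id"))
  cdm$visit_occurrence <- visit

  # map person -> own visit ids; persons without visits borrow a random visit
  # so linkage columns are never null
  for (tb in setdiff(names(EVENT_TABLES), "visit_occurrence")) {
    meta <- EVENT_TABLES[[tb]]
    set.seed(substream_seed(cfg$seed, tb))
    ne <- draw_event_counts(n, cfg$events[[tb]])
    total <- sum(ne)
    pid <- rep.int(seq_len(n), ne)
    ev <- data.table(id = seq_len(total), person_id = pid)
    setnames(ev, "id", meta$id)
    if (total_v > 0L) {
      vstart <- match(unique(visit$person_id), visit$person_id)
      first_visit <- rep(NA_integer_, n)
      first_visit[unique(visit$person_id)] <- vstart
      nvis <- tabulate(visit$person_id, nbins = n)
      off <- floor(runif(total) * pmax(nvis[pid], 1L))
      vidx <- ifelse(is.na(first_visit[pid]),
                     sample.int(total_v, total, replace = TRUE),
                     first_visit[pid] + off)
      ev[, visit_occurrence_id := visit$visit_occurrence_id[vidx]]
    } else {
      ev[, visit_occurrence_id := NA_integer_]
    }
    ev[[meta$start]] <- sample_dates(total, cfg$date_range)
    if (!is.null(meta$end)) {
      ev[[meta$end]] <- pmin(ev[[meta$start]] +
                               sample.int(cfg$end_offset_max + 1L, total, replace = TRUE) - 1L,
                             cfg$date_range[2])
    }
    if (!is.null(meta$concept)) {
      ev[[meta$concept]] <- sample_codes(total, vz[[meta$concept]], s)
    }
    cdm[[tb]] <- ev
  }

  structure(cdm, class = "cdm_tableset", config = cfg)
}

#' @export
print.cdm_tableset <- function(x, ...) {
  cat("<cdm_tableset>", length(x), "tables\n")
  for (nm in names(x)) cat(sprintf("  %-22s %8d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Write / read a CDM table set as CSV files
#'
#' One CSV per table, lower-snake-case headers, dates as ISO-8601
#' `YYYY-MM-DD`. `read_cdm()` also accepts a directory holding a real CDM
#' export (e.g. the SynPUF 5% release) with v5.x column names.
#'
#' @param cdm A `cdm_tableset` (or plain named list of data frames).
#' @param dir Directory to write to / read from.
#' @return `write_cdm()`: `dir` invisibly. `read_cdm()`: a `cdm_tableset`.
#' @export
write_cdm <- function(cdm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cdm)) {
    fwrite(as.data.table(cdm[[nm]]), file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_cdm
#' @export
read_cdm <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop_config("no CSV tables found in '%s'", dir)
  cdm <- lapply(files, function(f) {
    dt <- fread(f, keepLeadingZeros = TRUE)
    setnames(dt, normalize_name(names(dt)))
    for (col in grep("(_date|_datetime)$", names(dt), value = TRUE)) {
      if (is.character(dt[[col]]) || inherits(dt[[col]], "IDate"))
        set(dt, j = col, value = as.Date(dt[[col]]))
    }
    dt
  })
  names(cdm) <- normalize_name(sub("\\.csv$", "", basename(files)))
  structure(cdm, class = "cdm_tableset")
}
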