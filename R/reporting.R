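#' End-to-end experiment drivers
#'
#' The three `run_*` functions reproduce the report shapes of the study
#' design: a per-PHI full-data comparison (one row per PHI plus a column-mean
#' row), a per-scenario QI comparison at minimum cell sizes 1/2/5 with a
#' k = 1..20 distribution export, and a sample-size grid of paired sampling
#' experiments. Percentages are computed at full precision; rounding to three
#' decimals (half-even) happens only when reports are written.
#'
#' @name reporting
NULL

round3 <- function(x) round(x, 3)

append_average_row <- function(dt, label_col = "variable") {
  avg <- dt[, lapply(.SD, function(col) {
    if (is.numeric(col)) mean(col, na.rm = TRUE) else NA
  })]
  avg[[label_col]] <- "Average"
  if ("n_records" %in% names(avg)) avg[["n_records"]] <- NA_real_
  rbind(dt, avg, fill = TRUE)
}

#' Full-data PHI risk experiment
#'
#' For each PHI in the registry: build the limited data set, apply safe
#' harbor, profile both, and report unique-record counts and percentages,
#' maximum EC sizes and trust-differential gaps, plus a footer row of column
#' means. Per-variable failures become error rows; the run continues.
#'
#' @param cdm A `cdm_tableset`.
#' @param registry A `schema_registry`.
#' @param k_max Passed to [risk_summary()].
#' @return A `data.table` with one row per PHI plus an `"Average"` row;
#'   attribute `"errors"` carries any per-variable failures, and attribute
#'   `"summaries"` the underlying `gap_result`s.
#' @export
run_phi_experiment <- function(cdm, registry = load_registry("synpuf5pct"),
                               k_max = 20L) {
  phis <- registry$variables[role == "PHI"]
  rows <- list(); errors <- list(); gaps <- list()
  for (i in seq_len(nrow(phis))) {
    spec <- phis[i]
    res <- tryCatch({
      ds <- build_phi_dataset(cdm, spec, registry)
      sh <- apply_policy(ds, "safe_harbor")
      g <- trust_gap(risk_summary(equivalence_profile(ds), k_max),
                     risk_summary(equivalence_profile(sh), k_max))
      gaps[[spec$column_name]] <- g
      data.table(
        variable = spec$column_name,
        n_records = ds$n_records,
        n_dropped = ds$n_dropped,
        limited_unique = g$limited$unique_records,
        limited_unique_pct = g$limited$unique_percent,
        limited_max_ec = g$limited$max_ec_size,
        safe_unique = g$safe_harbor$unique_records,
        safe_unique_pct = g$safe_harbor$unique_percent,
        safe_max_ec = g$safe_harbor$max_ec_size,
        gap_unique_pct = g$gap_unique_percent,
        gap_max_ec = g$gap_max_ec
      )
    }, error = function(e) {
      errors[[spec$column_name]] <<- conditionMessage(e)
      data.table(variable = spec$column_name)
    })
    rows[[i]] <- res
  }
  if (length(errors) == nrow(phis))
    stop_config("every PHI failed: %s", paste(unlist(errors), collapse = "; "))
  out <- append_average_row(rbindlist(rows, fill = TRUE))
  setattr(out, "errors", errors)
  setattr(out, "summaries", gaps)
  out[]
}

#' Full-data QI scenario experiment
#'
#' For each clinical scenario: build the limited data set, apply safe harbor,
#' and report the percent (and record count) at minimum cell sizes 1, 2 and 5
#' for both policies with their gaps, plus a `k = 1..k_max` distribution
#' table for plotting.
#'
#' @param cdm A `cdm_tableset`.
#' @param registry A `schema_registry`.
#' @param scenarios List of `scenario_spec`s (default [default_scenarios()]).
#' @param k_report Cell sizes reported per scenario row (default 1, 2, 5).
#' @param k_max Range of the distribution export.
#' @return A `data.table` with one row per scenario plus an `"Average"` row;
#'   attribute `"distribution"` holds the long table
#'   (dataset, policy, k, percent) for k = 1..`k_max`.
#' @export
run_qi_experiment <- function(cdm, registry = load_registry("synpuf5pct"),
                              scenarios = default_scenarios(),
                              k_report = c(1L, 2L, 5L), k_max = 20L) {
  rows <- list(); dist <- list(); errors <- list()
  for (sc in scenarios) {
    res <- tryCatch({
      ds <- build_scenario_dataset(cdm, sc, registry)
      sh <- apply_policy(ds, "safe_harbor")
      pl <- risk_summary(equivalence_profile(ds), k_max)
      ps <- risk_summary(equivalence_profile(sh), k_max)
      dist[[sc$name]] <- rbind(
        data.table(dataset = sc$name, policy = "limited",
                   k = seq_len(k_max), percent = unname(pl$percent_at_size)),
        data.table(dataset = sc$name, policy = "safe_harbor",
                   k = seq_len(k_max), percent = unname(ps$percent_at_size))
      )
      row <- data.table(scenario = sc$name, n_records = ds$n_records,
                        n_dropped = ds$n_dropped)
      for (k in k_report) {
        kk <- as.character(k)
        row[[paste0("limited_pct_", k)]] <- pl$percent_at_size[[kk]]
        row[[paste0("limited_rec_", k)]] <- pl$records_at_size[[kk]]
        row[[paste0("safe_pct_", k)]] <- ps$percent_at_size[[kk]]
        row[[paste0("safe_rec_", k)]] <- ps$records_at_size[[kk]]
        row[[paste0("gap_pct_", k)]] <-
          pl$percent_at_size[[kk]] - ps$percent_at_size[[kk]]
      }
      row
    }, error = function(e) {
      errors[[sc$name]] <<- conditionMessage(e)
      data.table(scenario = sc$name)
    })
    rows[[sc$name]] <- res
  }
  if (length(errors) == length(scenarios))
    stop_config("every scenario failed: %s", paste(unlist(errors), collapse = "; "))
  out <- append_average_row(rbindlist(rows, fill = TRUE), "scenario")
  setattr(out, "distribution", rbindlist(dist))
  setattr(out, "errors", errors)
  out[]
}

#' Paired sampling experiment grid
#'
#' Runs [paired_sample_experiment()] for every dataset over a grid of sample
#' sizes. Cells where the sample size exceeds the dataset are marked skipped.
#' Each sample-size block gets an `"Average"` row over its non-skipped cells.
#'
#' @param datasets Named list of limited `analysis_dataset`s (e.g. one per
#'   scenario or per PHI).
#' @param sample_sizes Integer vector of sample sizes
#'   (default `c(1e3, 1e4, 1e5, 1e6)`).
#' @param iterations Draws per cell (default 100).
#' @param seed Master seed.
#' @param policy Policy applied to produce the safe-harbor image.
#' @return A `data.table` with one row per (sample size, dataset) cell plus
#'   per-size average rows.
#' @export
run_sampling_experiment <- function(datasets,
                                    sample_sizes = c(1e3, 1e4, 1e5, 1e6),
                                    iterations = 100L, seed = 1L,
                                    policy = "safe_harbor") {
  blocks <- list()
  for (n in sample_sizes) {
    rows <- list()
    for (nm in names(datasets)) {
      ds <- datasets[[nm]]
      sh <- apply_policy(ds, policy)
      r <- paired_sample_experiment(ds, sh, n = n, iterations = iterations,
                                    seed = seed)
      rows[[nm]] <- if (isTRUE(r$skipped)) {
        data.table(sample_size = n, dataset = nm, skipped = TRUE)
      } else {
        data.table(
          sample_size = n, dataset = nm, skipped = FALSE,
          limited_mean = r$limited$mean_unique, limited_sd = r$limited$sd_unique,
          limited_pct = r$limited$percent,
          safe_mean = r$safe_harbor$mean_unique, safe_sd = r$safe_harbor$sd_unique,
          safe_pct = r$safe_harbor$percent,
          gap_pct = r$gap_percent
        )
      }
    }
    block <- rbindlist(rows, fill = TRUE)
    done <- block[skipped == FALSE]
    if (nrow(done)) {
      avg <- data.table(sample_size = n, dataset = "Average", skipped = FALSE,
                        limited_pct = mean(done$limited_pct),
                        safe_pct = mean(done$safe_pct),
                        gap_pct = mean(done$gap_pct))
      block <- rbind(block, avg, fill = TRUE)
    }
    blocks[[as.character(n)]] <- block
  }
  rbindlist(blocks, fill = TRUE)[]
}

#' Run the whole pipeline from a config
#'
#' Generates (or reads) a CDM, runs the PHI, QI and sampling experiments, and
#' writes the report tables as CSVs with a JSON manifest.
#'
#' @param config A list or path of a YAML document with keys:
#'   `input` (either `synthetic: <synthetic_config args>` or `cdm_dir:`),
#'   `profile` (registry profile, default `"synpuf5pct"`),
#'   `sample_sizes`, `iterations`, `seed`, `out_dir`.
#' @return Invisibly, a list with elements `phi`, `qi`, `sampling`,
#'   `distribution` and `cdm`.
#' @export
run_privacy_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  registry <- load_registry(config$profile %||% "synpuf5pct")
  cdm <- if (!is.null(config$input$cdm_dir)) {
    read_cdm(config$input$cdm_dir)
  } else {
    args <- config$input$synthetic %||% list()
    args$seed <- args$seed %||% seed
    generate_cdm(do.call(synthetic_config, args))
  }
  phi <- run_phi_experiment(cdm, registry)
  qi <- run_qi_experiment(cdm, registry)
  scen <- lapply(default_scenarios(),
                 function(sc) build_scenario_dataset(cdm, sc, registry))
  samp <- run_sampling_experiment(
    scen,
    sample_sizes = unlist(config$sample_sizes %||% c(1e3, 1e4, 1e5, 1e6)),
    iterations = as.integer(config$iterations %||% 100L),
    seed = seed
  )
  out <- list(phi = phi, qi = qi, sampling = samp,
              distribution = attr(qi, "distribution"), cdm = cdm)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    num <- function(dt) {
      dt <- copy(dt)
      for (col in names(dt)) if (is.numeric(dt[[col]]))
        set(dt, j = col, value = round3(dt[[col]]))
      dt
    }
    fwrite(num(phi), file.path(config$out_dir, "phi_experiment.csv"))
    fwrite(num(qi), file.path(config$out_dir, "qi_experiment.csv"))
    fwrite(num(samp), file.path(config$out_dir, "sampling_experiment.csv"))
    fwrite(num(attr(qi, "distribution")),
           file.path(config$out_dir, "cell_size_distribution.csv"))
    manifest <- list(
      seed = seed, profile = registry$profile_name,
      tables = lapply(cdm, nrow),
      datasets = lapply(scen, function(d)
        list(n_records = d$n_records, n_dropped = d$n_dropped,
             columns = names(d$data)))
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}
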