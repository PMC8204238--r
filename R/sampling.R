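#' Paired random-sampling experiments
#'
#' Full-data uniqueness percentages depend strongly on how many records a
#' variable happens to have, so risk between variables is also compared at an
#' equal record count: draw n records at random, count the unique ones,
#' repeat (100 iterations by default), and average. Sampling is paired by
#' default -- one index set per iteration applied to both the limited and
#' safe-harbor datasets, which are row-aligned images of each other -- so the
#' per-iteration gap inherits the coarsening guarantee (it is never
#' negative) and between-dataset sampling noise cancels. An unpaired mode is
#' available for sensitivity analysis.
#'
#' @name sampling
NULL

count_unique_records <- function(dt, idx) {
  sub <- dt[idx]
  cnt <- sub[, .N, by = names(sub)]
  as.numeric(sum(cnt$N[cnt$N == 1L]))
}

new_sample_summary <- function(n, iterations, uniques) {
  structure(
    list(n = n, iterations = iterations,
         mean_unique = mean(uniques),
         sd_unique = if (iterations > 1L) sd(uniques) else 0,
         percent = 100 * mean(uniques) / n),
    class = "sample_summary"
  )
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("<sample_summary> n = %s x %d iterations: mean unique %.3f (SD %.3f), %.3f%%\n",
              format(x$n, big.mark = ","), x$iterations, x$mean_unique,
              x$sd_unique, x$percent))
  invisible(x)
}

#' Run a paired sampling experiment on a limited / safe-harbor pair
#'
#' @param limited An `analysis_dataset` at the limited level.
#' @param safe Its row-aligned safe-harbor image (same name, same
#'   `n_records`), e.g. from [apply_policy()].
#' @param n Sample size, drawn without replacement; must not exceed
#'   `n_records` (larger requests are recorded as skipped, not fatal).
#' @param iterations Number of repeated draws (default 100).
#' @param seed Master seed; iteration r draws from a substream keyed on
#'   (seed, dataset name, n, r), so results are stable under reordering of
#'   experiments.
#' @param paired If `TRUE` (default) the same index set is applied to both
#'   datasets per iteration; if `FALSE` each dataset is sampled
#'   independently.
#' @return A `paired_sample_result`: `sample_summary` for each dataset,
#'   `gap_percent = limited$percent - safe$percent`, and a `skipped` flag.
#' @examples
#' cdm <- generate_cdm(cdm_presets(seed = 1)$toy)
#' ds <- build_phi_dataset(cdm, "visit_start_date")
#' sh <- apply_policy(ds, "safe_harbor")
#' paired_sample_experiment(ds, sh, n = 20, iterations = 10, seed = 1)
#' @export
paired_sample_experiment <- function(limited, safe, n, iterations = 100L,
                                     seed = 1L, paired = TRUE) {
  stopifnot(inherits(limited, "analysis_dataset"),
            inherits(safe, "analysis_dataset"))
  if (n <= 0) stop_config("sample size must be positive")
  if (limited$n_records != safe$n_records)
    stop_config("datasets are not row-aligned: %d vs %d records",
                limited$n_records, safe$n_records)
  N <- limited$n_records
  if (n > N) {
    message(sprintf("skipping %s: sample size %s exceeds %s records",
                    limited$name, format(n, big.mark = ","),
                    format(N, big.mark = ",")))
    return(structure(list(name = limited$name, n = n, skipped = TRUE),
                     class = "paired_sample_result"))
  }
  n <- as.integer(n); iterations <- as.integer(iterations)
  u_lim <- numeric(iterations); u_safe <- numeric(iterations)
  for (r in seq_len(iterations)) {
    set.seed(substream_seed(seed, limited$name, n, r))
    idx <- sample.int(N, n)
    u_lim[r] <- count_unique_records(limited$data, idx)
    if (!paired) {
      set.seed(substream_seed(seed, limited$name, n, r, "unpaired"))
      idx <- sample.int(N, n)
    }
    u_safe[r] <- count_unique_records(safe$data, idx)
  }
  lim_sum <- new_sample_summary(n, iterations, u_lim)
  safe_sum <- new_sample_summary(n, iterations, u_safe)
  structure(
    list(name = limited$name, n = n, skipped = FALSE,
         limited = lim_sum, safe_harbor = safe_sum,
         gap_percent = lim_sum$percent - safe_sum$percent),
    class = "paired_sample_result"
  )
}

#' @export
print.paired_sample_result <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat(sprintf("<paired_sample_result> '%s' n = %s: skipped (n exceeds records)\n",
                x$name, format(x$n, big.mark = ",")))
  } else {
    cat(sprintf("<paired_sample_result> '%s' n = %s: limited %.3f%%, safe harbor %.3f%%, gap %.3f\n",
                x$name, format(x$n, big.mark = ","), x$limited$percent,
                x$safe_harbor$percent, x$gap_percent))
  }
  invisible(x)
}

#' Average trust-differential gaps across experiments
#'
#' @param gaps Numeric vector of per-variable or per-scenario gap
#'   percentages (non-empty; `NA`s from skipped cells removed with
#'   `na.rm = TRUE`).
#' @param na.rm Drop missing entries before averaging.
#' @return The arithmetic mean gap.
#' @examples
#' mean_gap(c(29.869, 44.871, 89.917, 76.263, 80.274, 99.212, 96.182))
#' @export
mean_gap <- function(gaps, na.rm = TRUE) {
  if (!length(gaps)) stop_config("cannot average an empty set of gaps")
  if (na.rm) gaps <- gaps[!is.na(gaps)]
  if (!length(gaps)) stop_config("all gaps are missing")
  mean(gaps)
}
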