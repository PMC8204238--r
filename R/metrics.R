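#' Equivalence-class profiles and risk summaries
#'
#' An equivalence class (EC) is a maximal set of records identical on all
#' selected analysis columns. A dataset's privacy risk is summarised from the
#' histogram of EC sizes: the fraction of records in classes of size one
#' (unique, maximally re-identifiable records), the fraction at any given
#' "minimum cell size" k, and the maximum EC size (the largest
#' indistinguishable group). Comparing the same summary between two
#' deidentification levels of the same data yields the trust-differential
#' gap: how much risk the stricter policy removes.
#'
#' @name risk_metrics
NULL

#' Construct an EC profile from a size histogram
#'
#' Used both internally and to evaluate the metrics on published class
#' counts. The conservation law `sum(size * classes) == n_records` is
#' enforced.
#'
#' @param histogram A `data.frame` with columns `size` (class size k >= 1)
#'   and `classes` (number of classes of that size, >= 1), or a named vector
#'   `c("1" = c1, "2" = c2, ...)`.
#' @param n_records Total record count; defaults to `sum(size * classes)`.
#' @param columns Optional character vector recording the grouping columns.
#' @return An `ec_profile` object.
#' @examples
#' ec_profile(c("1" = 2, "2" = 1))            # rows {A, A, B, C}
#' ec_profile(data.frame(size = 4, classes = 1))
#' @export
ec_profile <- function(histogram, n_records = NULL, columns = NULL) {
  if (!is.data.frame(histogram)) {
    histogram <- data.table(size = as.integer(names(histogram)),
                            classes = as.numeric(histogram))
  }
  hist <- as.data.table(histogram)[, .(size = as.integer(size),
                                       classes = as.numeric(classes))]
  hist <- hist[classes > 0]
  if (nrow(hist) && (anyNA(hist$size) || any(hist$size < 1)))
    stop_config("EC sizes must be integers >= 1")
  if (anyDuplicated(hist$size)) stop_config("duplicate EC size in histogram")
  setorder(hist, size)
  implied <- sum(hist$size * hist$classes)
  n_records <- n_records %||% implied
  if (!isTRUE(all.equal(implied, n_records)))
    stop_config("EC histogram violates conservation: sum(k * c_k) = %s but n_records = %s",
                format(implied), format(n_records))
  structure(list(histogram = hist, n_records = as.numeric(n_records),
                 columns = columns),
            class = "ec_profile")
}

#' @export
print.ec_profile <- function(x, ...) {
  cat(sprintf("<ec_profile> %s records, %d class sizes (max EC %s)\n",
              format(x$n_records, big.mark = ","), nrow(x$histogram),
              if (nrow(x$histogram)) max(x$histogram$size) else NA))
  invisible(x)
}

#' Profile the equivalence classes of a dataset
#'
#' Groups records by the selected columns in a single hash-group pass (no
#' pairwise work), then histograms the group sizes. Values are compared as
#' raw tokens after whitespace trimming; missing values form their own level.
#'
#' @param dataset An `analysis_dataset`, or any data frame.
#' @param columns Columns to group on; default all analysis columns.
#' @return An `ec_profile`.
#' @examples
#' equivalence_profile(data.frame(x = c("A", "A", "B", "C")))
#' @export
equivalence_profile <- function(dataset, columns = NULL) {
  dt <- if (inherits(dataset, "analysis_dataset")) dataset$data else as.data.table(dataset)
  dt <- as.data.table(dt)
  columns <- columns %||% names(dt)
  if (!length(columns)) stop_config("empty column selection")
  missing_cols <- setdiff(columns, names(dt))
  if (length(missing_cols))
    stop_config("columns not in dataset: %s", paste(missing_cols, collapse = ", "))
  sub <- dt[, columns, with = FALSE]
  for (col in names(sub)) {
    if (is.character(sub[[col]])) set(sub, j = col, value = trimws(sub[[col]]))
  }
  sizes <- sub[, .N, by = names(sub)]
  hist <- sizes[, .(classes = as.numeric(.N)), by = .(size = N)]
  setorder(hist, size)
  ec_profile(hist, n_records = nrow(sub), columns = columns)
}

#' Percent of records at a given minimum cell size
#'
#' Reports the share of records that sit in equivalence classes of size
#' exactly `k` (the exact-size convention): `100 * k * c_k / N`. With
#' `cumulative = TRUE` it instead reports records in classes of size at most
#' `k`.
#'
#' @param profile An `ec_profile`.
#' @param k Class size(s), integer >= 1 (vectorised).
#' @param cumulative Report classes of size <= k instead of exactly k.
#' @return Percentage(s) in `[0, 100]`; 0 for absent sizes.
#' @examples
#' p <- ec_profile(c("1" = 2, "2" = 1))
#' percent_at_size(p, 1:2)
#' @export
percent_at_size <- function(profile, k, cumulative = FALSE) {
  stopifnot(inherits(profile, "ec_profile"))
  if (any(k < 1)) stop_config("minimum cell size k must be >= 1")
  k <- as.integer(k)
  h <- profile$histogram
  if (profile$n_records == 0) stop_config("profile has no records")
  records_at <- function(ki) {
    if (cumulative) sum(h[size <= ki, size * classes])
    else sum(h[size == ki, size * classes])
  }
  100 * vapply(k, records_at, numeric(1)) / profile$n_records
}

#' Percent of unique records
#'
#' `100 * c_1 / N`: the share of records in equivalence classes of size one,
#' i.e. singled out exactly by the analysis columns.
#'
#' @param profile An `ec_profile` with at least one record.
#' @return A percentage in `[0, 100]`.
#' @examples
#' unique_record_percent(ec_profile(c("1" = 1141, "2" = 7)))  # 98.787...
#' @export
unique_record_percent <- function(profile) {
  stopifnot(inherits(profile, "ec_profile"))
  if (profile$n_records < 1) stop_config("profile has no records")
  percent_at_size(profile, 1L)
}

#' Largest equivalence-class size
#'
#' @param profile A non-empty `ec_profile`.
#' @return The largest class size present.
#' @export
max_ec_size <- function(profile) {
  stopifnot(inherits(profile, "ec_profile"))
  if (!nrow(profile$histogram)) stop_config("profile is empty")
  max(profile$histogram$size)
}

#' Summarise a profile as a risk summary
#'
#' @param profile An `ec_profile`.
#' @param k_max Largest minimum cell size to tabulate (default 20, the upper
#'   end of thresholds used for highly sensitive data).
#' @return A `risk_summary`: percent and record count at each size 1..`k_max`,
#'   the unique-record percent, maximum EC size, and `n_records`.
#' @export
risk_summary <- function(profile, k_max = 20L) {
  stopifnot(inherits(profile, "ec_profile"))
  if (k_max < 1) stop_config("k_max must be >= 1")
  ks <- seq_len(k_max)
  pct <- percent_at_size(profile, ks)
  h <- profile$histogram
  recs <- vapply(ks, function(ki) sum(h[size == ki, size * classes]), numeric(1))
  structure(
    list(percent_at_size = stats::setNames(pct, ks),
         records_at_size = stats::setNames(recs, ks),
         unique_percent = pct[1],
         unique_records = recs[1],
         max_ec_size = max_ec_size(profile),
         n_records = profile$n_records,
         columns = profile$columns),
    class = "risk_summary"
  )
}

#' @export
print.risk_summary <- function(x, ...) {
  cat(sprintf("<risk_summary> N = %s; unique %.3f%%; max EC %d\n",
              format(x$n_records, big.mark = ","), x$unique_percent,
              x$max_ec_size))
  invisible(x)
}

#' Trust-differential gap between two deidentification levels
#'
#' The gap is the element-wise difference in percent-at-size between the
#' less deidentified (limited) and more deidentified (safe harbor) summaries,
#' plus the increase in maximum EC size. When the safe-harbor summary is the
#' masked image of the limited one, coarsening guarantees a non-negative
#' unique-record gap and max-EC gap.
#'
#' @param limited,safe `risk_summary` objects over the same columns roles.
#' @return A `gap_result` keeping both inputs, `gap_percent_at_size`,
#'   `gap_unique_percent` and `gap_max_ec`.
#' @examples
#' lim <- risk_summary(ec_profile(c("1" = 865840, "70" = 4993),
#'   n_records = 865840 + 70 * 4993))
#' @export
trust_gap <- function(limited, safe) {
  stopifnot(inherits(limited, "risk_summary"), inherits(safe, "risk_summary"))
  if (!is.null(limited$columns) && !is.null(safe$columns) &&
      !setequal(limited$columns, safe$columns))
    stop_config("risk summaries computed over different column sets")
  ks <- intersect(names(limited$percent_at_size), names(safe$percent_at_size))
  structure(
    list(limited = limited, safe_harbor = safe,
         gap_percent_at_size = limited$percent_at_size[ks] - safe$percent_at_size[ks],
         gap_unique_percent = limited$unique_percent - safe$unique_percent,
         gap_max_ec = safe$max_ec_size - limited$max_ec_size),
    class = "gap_result"
  )
}

#' @export
print.gap_result <- function(x, ...) {
  cat(sprintf("<gap_result> unique-record gap %.3f points; max-EC gap %d\n",
              x$gap_unique_percent, x$gap_max_ec))
  invisible(x)
}
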