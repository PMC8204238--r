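#' Deidentification policies
#'
#' Two standard policies are provided. The `limited` policy is the identity:
#' it reflects data already at the HIPAA limited-data-set level, where exact
#' dates and some geography are retained. The `safe_harbor` policy removes
#' the HIPAA identifier categories: every date-kind PHI is generalised from
#' `YYYY-MM-DD` to the year token `YYYY-**-**`, every other PHI (birth month
#' and day, provider NPI, county) is suppressed to the shared constant token
#' `*`, and QIs pass through untouched. Suppression to one shared token (not
#' to missing) means a fully masked column contributes nothing to record
#' distinguishability.
#'
#' @param name `"limited"`, `"safe_harbor"`, or `"custom"`.
#' @param overrides Named character vector mapping column names to rules
#'   (`"year_only"`, `"suppress"`, `"none"`), consulted before the role-based
#'   default; required for `"custom"`.
#' @return A `mask_policy` object.
#' @examples
#' mask_policy("safe_harbor")
#' @export
mask_policy <- function(name = c("limited", "safe_harbor", "custom"),
                        overrides = character()) {
  name <- match.arg(name)
  if (name == "custom" && !length(overrides))
    stop_config("a custom policy needs at least one override rule")
  stopifnot(all(overrides %in% VALID_RULES))
  structure(list(name = name, overrides = overrides), class = "mask_policy")
}

#' @export
print.mask_policy <- function(x, ...) {
  cat(sprintf("<mask_policy> %s (%d overrides)\n", x$name, length(x$overrides)))
  invisible(x)
}

# Rule applied to one column under a policy, given its variable spec.
policy_rule <- function(policy, spec) {
  col <- spec$column_name
  if (col %in% names(policy$overrides)) return(unname(policy$overrides[[col]]))
  if (policy$name == "limited") return("none")
  # safe harbor / custom default: the registry's per-variable mask rule,
  # which is year_only for date PHIs, suppress for other PHIs, none otherwise
  spec$mask_rule
}

MASKED_DATE_RE <- "^\\d{4}-\\*\\*-\\*\\*$"

#' Mask a vector of values under one rule
#'
#' `year_only` turns an ISO date `YYYY-MM-DD` into the token `YYYY-**-**`;
#' `suppress` replaces every non-missing value with the constant token `*`;
#' `none` is the identity. Missing values pass through unchanged under every
#' rule, and already-masked `YYYY-**-**` tokens are fixed points of
#' `year_only`, so masking is idempotent.
#'
#' @param value Vector of values (dates, codes or character).
#' @param rule `"year_only"`, `"suppress"` or `"none"`.
#' @param context Optional label (column name) used in error messages.
#' @return The masked vector (`character` for the two masking rules).
#' @examples
#' mask_value("2008-03-14", "year_only")
#' mask_value("1234567890", "suppress")
#' @export
mask_value <- function(value, rule = c("none", "year_only", "suppress"),
                       context = "value") {
  rule <- match.arg(rule)
  if (rule == "none") return(value)
  if (rule == "suppress") {
    out <- rep("*", length(value))
    out[is.na(value)] <- NA_character_
    return(out)
  }
  # year_only
  chr <- if (inherits(value, c("Date", "IDate"))) format(value, "%Y-%m-%d")
         else as.character(value)
  ok <- is.na(chr) | grepl("^\\d{4}-\\d{2}-\\d{2}", chr) | grepl(MASKED_DATE_RE, chr)
  if (!all(ok)) {
    bad <- which(!ok)
    stop_config("cannot year-mask unparseable date in %s (rows %s; e.g. '%s')",
                context, paste(head(bad, 5), collapse = ", "), chr[bad[1]])
  }
  out <- ifelse(grepl(MASKED_DATE_RE, chr), chr,
                paste0(substr(chr, 1, 4), "-**-**"))
  out[is.na(chr)] <- NA_character_
  out
}

#' Apply a deidentification policy to an analysis dataset
#'
#' Transforms each PHI column by its masking rule, leaving row count and row
#' order untouched: row `i` of the output is the masked image of row `i` of
#' the input (required for paired sampling). Because masking maps equal
#' values to equal tokens, the masked dataset's equivalence-class partition
#' is a coarsening of the original's.
#'
#' @param dataset An `analysis_dataset`.
#' @param policy A `mask_policy` or policy name.
#' @return A new `analysis_dataset` with `policy` recorded.
#' @examples
#' cdm <- generate_cdm(cdm_presets(seed = 1)$toy)
#' ds <- build_phi_dataset(cdm, "death_date")
#' apply_policy(ds, "safe_harbor")
#' @export
apply_policy <- function(dataset, policy = "safe_harbor") {
  stopifnot(inherits(dataset, "analysis_dataset"))
  if (is.character(policy)) policy <- mask_policy(policy)
  data <- copy(dataset$data)
  for (i in seq_len(nrow(dataset$columns))) {
    spec <- dataset$columns[i]
    col <- spec$column_name
    rule <- policy_rule(policy, spec)
    if (rule != "none" && col %in% names(data)) {
      set(data, j = col, value = mask_value(data[[col]], rule, context = col))
    }
  }
  new_analysis_dataset(dataset$name, data, dataset$columns,
                       n_dropped = dataset$n_dropped, policy = policy$name)
}
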