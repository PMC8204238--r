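# Internal helpers: stable substream seeding and small utilities.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Polynomial string hash modulo the Mersenne prime 2^31 - 1. All arithmetic
# stays below 2^53, so doubles are exact.
str_hash31 <- function(s) {
  p <- 2147483647
  h <- 0
  for (ch in utf8ToInt(enc2utf8(s))) h <- (h * 131 + ch) %% p
  h
}

#' Derive a reproducible substream seed
#'
#' Combines a master seed with an arbitrary set of labels (table names,
#' dataset names, sample sizes, iteration indices) into a stable 31-bit seed.
#' The same master seed and labels always yield the same substream, so adding
#' or reordering independent components of a run does not perturb the others.
#'
#' @param master Integer master seed.
#' @param ... Labels coerced to character and hashed into the stream id.
#' @return An integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @examples
#' substream_seed(42, "visit_occurrence")
#' substream_seed(42, "death", 1000, 7)
#' @export
substream_seed <- function(master, ...) {
  p <- 2147483647
  labels <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                         character(1)), collapse = "|")
  as.integer((as.numeric(master) %% p * 48271 + str_hash31(labels)) %% p)
}

# Normalize CDM column/table identifiers: lower snake_case.
normalize_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[^a-z0-9]+", "_", x)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
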