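#' Published reference statistics for the SynPUF 5% study dataset
#'
#' Desk-scale reference numbers published for the SynPUF 5% OMOP CDM (v5.2.2)
#' privacy-risk study: per-PHI unique-record counts and maximum EC sizes
#' under both policies, per-scenario class counts at minimum cell sizes
#' 1/2/5, and the paired-sampling means over 100 iterations at sample sizes
#' 10^3..10^6. They are inputs for verifying the metric definitions against
#' printed numerators and denominators without downloading the release
#' (`vignette("privacy-risk-quantification")` shows the worked examples).
#'
#' @param which One of `"phi"` (per-variable full-data comparison),
#'   `"scenario"` (per-scenario cell-size table), `"sampling"` (scenario
#'   sampling grid), `"phi_sampling"` (per-PHI 1000-sample block).
#' @return A `data.table`. Column naming follows the `run_*` report tables:
#'   `*_unique` are unique-record counts, `*_pct` percentages, `*_max_ec`
#'   maximum EC sizes, `*_classes_k` the published equivalence-class counts
#'   at cell size k, `gap_*` published trust-differential gaps; for the
#'   sampling tables `*_mean`/`*_sd` are the mean/SD of unique records over
#'   the 100 iterations.
#' @examples
#' ref <- synpuf_reference("phi")
#' ref[variable == "death_date", .(n_records, limited_unique)]
#' @export
synpuf_reference <- function(which = c("phi", "scenario", "sampling",
                                       "phi_sampling")) {
  which <- match.arg(which)
  file <- switch(which,
    phi = "synpuf_phi_reference.csv",
    scenario = "synpuf_scenario_reference.csv",
    sampling = "synpuf_sampling_reference.csv",
    phi_sampling = "synpuf_phi_sampling_reference.csv"
  )
  path <- system.file("extdata", file, package = "cdmprivacy")
  fread(path)
}
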