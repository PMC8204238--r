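---
title: "Quantifying PHI and QI privacy risk in an OMOP CDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PHI and QI privacy risk in an OMOP CDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdmprivacy)
library(data.table)
```

## The problem

Distributed research networks standardise multi-institutional clinical data
into a common data model (the OMOP CDM) and share only analysis results, not
patient-level rows. The structure nevertheless retains personal health
identifiers (PHIs) -- event dates, birth month/day, county, provider NPI --
and quasi-identifiers (QIs) such as year of birth, gender, race, ethnicity,
state and clinical order codes whose combination can single a patient out.
`cdmprivacy` measures that residual risk and how much of it a stricter
deidentification policy removes.

The measurement design is:

1. **Registry.** Map CDM columns to privacy roles. The `synpuf5pct` profile
   hard-codes the 16 PHIs and 12 QIs present without nulls in the SynPUF 5%
   release (CDM v5.2.2); the `omop_full` profile ships as an editable YAML
   reconstruction over the full CDM with 45 PHIs and 17 QIs.
2. **Datasets.** For each PHI, a 6-column *limited data set* (the PHI plus
   the five common demographics: year of birth, gender, race, ethnicity,
   state). For the QI experiment, seven clinical-scenario data sets
   (diagnosis, procedure, drug treatment, lab test, device treatment, death,
   medical history), each the scenario's event table joined to 11 common
   variables plus its own date PHIs and concept-id QI (14 columns for
   diagnosis).
3. **Masking.** The *safe harbor* policy generalises every date PHI from
   `YYYY-MM-DD` to `YYYY-**-**` and suppresses every other PHI to the shared
   token `*`; QIs pass through. The *limited* policy is the identity.
4. **Metrics.** Equivalence classes (ECs) are maximal sets of records
   identical on all analysis columns. Risk is summarised by the percentage
   of records at a *minimum cell size* `k` (exactly `k`-sized classes), the
   unique-record percentage (`k = 1`), and the maximum EC size. The *trust
   differential gap* is the difference of a metric between the limited and
   safe-harbor versions of the same data.
5. **Sampling.** Because uniqueness depends strongly on the record count,
   risk is also compared at equal `n`: draw `n` records without replacement,
   count the unique ones, repeat 100 times, and average.

## A worked run

```{r run}
cdm <- generate_cdm(cdm_presets(seed = 42)$toy)
ds  <- build_phi_dataset(cdm, "visit_start_date")
sh  <- apply_policy(ds, "safe_harbor")
trust_gap(risk_summary(equivalence_profile(ds)),
          risk_summary(equivalence_profile(sh)))
```

`run_phi_experiment()`, `run_qi_experiment()` and
`run_sampling_experiment()` assemble the full report tables;
`run_privacy_pipeline()` drives all stages from one config and writes CSVs
plus a JSON manifest.

## Metric conventions

* **Exact-size convention.** `percent_at_size(p, k)` reports
  `100 * k * c_k / N`, the share of records in classes of exactly size `k`.
  This matches the published per-scenario tables for the SynPUF 5% study
  dataset, which can be verified from their printed class counts, e.g.
  `186,162` size-2 classes over `3,369,468` diagnosis records give
  `11.049%`:

```{r convention}
dg <- synpuf_reference("scenario")[scenario == "diagnosis"]
p  <- ec_profile(data.frame(size = c(2, dg$n_records - 2 * dg$limited_classes_2),
                            classes = c(dg$limited_classes_2, 1)))
percent_at_size(p, 2)
```

  A cumulative mode (`cumulative = TRUE`, classes of size at most `k`) is
  available; the published per-scenario gap columns at `k = 2` follow that
  cumulative convention even though the percentage columns are exact-size.
* **Rounding.** All computation is at full floating precision; reports round
  half-even to 3 decimals at the presentation layer only. Published
  percentages mix truncation and rounding (`98.7879` printed as `98.787`),
  so every comparison against a printed value uses a tolerance of 0.005
  percentage points (0.002 where the check is a single division).
* **Token grouping.** Values are grouped as raw tokens after whitespace
  trimming; missing values form their own level. Suppression writes one
  shared token rather than a missing value, so a fully suppressed column
  contributes nothing to distinguishability.
* **Idempotence.** `YYYY-**-**` tokens are fixed points of the year rule,
  so applying safe harbor twice equals applying it once.

## The synthetic generator

No public fixture accompanies the package, so the generator produces CDM
tables with the *structure* the analysis is sensitive to, while making no
claim of clinical plausibility:

* a fixed 3-year event window (2008--2010 by default), event dates uniform
  within it, end dates equal to start dates plus a uniform 0--30-day offset;
* per-table event multiplicity: exactly one death date per deceased person
  versus Poisson-distributed visits, conditions, procedures, drugs, devices,
  measurements and observations per person;
* `day_of_birth` constant at 1 (the source field arrives pre-generalised),
  which makes that PHI's limited and safe-harbor datasets structurally
  identical -- the zero-gap statistical baseline;
* codes drawn from a rank-skewed (Zipf-like, exponent 1 by default)
  distribution over configurable vocabulary sizes -- defaults gender 2,
  race 5, ethnicity 2, state 50, county 300, order codes 100--1000, chosen
  as realistic cardinalities for US claims-like data;
* one master seed with per-table substreams derived by stable string
  hashing, so output is byte-reproducible and adding a table does not
  perturb the others.

The `synpuf_like` preset is calibrated to the published study sizes: 25,200
persons, death fraction `1155/25200`, and per-table Poisson rates equal to
each published table total divided by 25,200 (visits 48.4, conditions 128.2,
procedures 120.0, measurements 29.4, observations 16.7, drug exposures 6.3,
device exposures 1.9). Tests and the acceptance script run the same
structure at reduced person counts (150--2,000 persons), a problem size at
which the qualitative contrasts below are stable while a full run stays in
seconds-to-minutes territory.

What the generator deliberately does **not** emulate: diagnosis--drug
coherence, longitudinal disease course, visit seasonality, realistic code
co-occurrence, or the exact per-table multiplicity distributions of the real
release (they are not published; the Poisson defaults are stated
assumptions). Passing tests therefore demonstrate correctness of the metrics
and the direction of structural effects, not numerical agreement with any
real dataset's risk levels.

## Design choices in genuinely open territory

Several composition details of the original study are not public; the
package fixes documented, overridable defaults:

* **Scenario composition.** Each scenario contributes its own table's
  start/end date PHIs and concept-id QI; the six common PHIs are
  `month_of_birth`, `day_of_birth`, `county`, `npi`, `visit_start_date`,
  `visit_end_date`. `place_of_service_concept_id` is assigned to the
  medical-history scenario, bringing the scenario-specific totals to 10 PHIs
  and 7 QIs. All of this is overridable via `scenario_spec()`.
* **Death scenario joins.** The death scenario is driven by the visit table
  left-joined to death (its published record total equals the visit count,
  not the death count). Missing death dates are kept as an explicit missing
  level rather than dropped; dropping them would collapse the dataset to
  deceased persons' visits and contradict the published total.
* **NPI dataset.** Driven by the visit table joined to provider (the
  published total, 1,215,317, is a visit-scale count). Person-level PHIs
  (birth fields, county) are person-driven.
* **Paired sampling.** One index set per iteration is applied to both
  datasets. Pairing is not stated in the published design, but it guarantees
  the per-iteration gap inherits the coarsening inequality (every gap
  non-negative, as the published tables exhibit) and removes between-dataset
  sampling noise; `paired = FALSE` exists for sensitivity analysis. Samples
  larger than the dataset are recorded as skipped. The SD uses the `n - 1`
  denominator over the 100 iteration counts.
* **Age-90 aggregation.** HIPAA's safe-harbor rule for ages over 89 is *not*
  applied to `year_of_birth`: the reference results keep year of birth as an
  untouched QI (the birth-day dataset retains 49 ECs after masking, which
  requires unaggregated years).

## Numerical notes and known inconsistencies

* Degenerate inputs: empty registries, empty event tables and single-row
  datasets are valid; a profile of zero records refuses percentage queries.
* The published per-variable table is internally inconsistent for the two
  visit-date rows: limited 63.310% minus safe-harbor 0.047% is 63.263, yet
  the printed gap is 62.952 (and the printed safe-harbor percentage 0.0395
  does not match its own count 581/1,218,881 = 0.0477). Consequently the
  published overall PHI mean gap 31.448 is the mean of the printed
  per-variable gap column; recomputing every gap from the printed counts
  gives 31.488.
* The published average of the max-EC gap column is printed as 771.937, but
  the arithmetic mean of the column's entries is 794.688. The package
  reports the column mean.
* The published class counts at cell sizes 2 and 5 are equivalence-class
  counts (their footnote calls them records, but only `k * c_k / N`
  reproduces the printed percentages).

## Scale

Profiling is a single hash-group pass (`data.table` grouping), linear up to
sorting: a 5-million-row, 14-column table profiles in minutes on one CPU.
The quadratic pairwise oracle used in the test suite is for verification
only and is kept at or below 1,000 rows.

## Reproducing the reference numbers

`scripts/acceptance.R` recomputes, at run time, every desk-scale metric
evaluation shown above from the published counts shipped in
`inst/extdata/synpuf_*.csv`, runs the reduced synthetic pipeline, and writes
all quantities as JSON. A full-scale replication against the real SynPUF 5%
release is supported as an integration path (download the CSV export and
point `read_cdm()` / the CLI's `--input-cdm` at it) but is not part of the
test suite.
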