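#' Pipeline threshold configuration
#'
#' Collects every tunable cut-off of the workflow in one validated object.
#' The allele-frequency maxima default to [max_credible_af()] of the
#' packaged ciliopathy [disease_model()] (0.002); the remaining defaults
#' are the workflow's operating points: splice delta score > 0.5, common-SV
#' cluster cut-off at 10 database occurrences, SV supporting-read fraction
#' > 0.30, SV reciprocal-overlap clustering at 0.8.
#'
#' Boundary semantics, fixed across the pipeline: allele-frequency
#' retention is strict (`af < cohort_af_max`), splice retention is strict
#' (`delta > splice_delta_min`), SV rarity is strict
#' (`occurrences < sv_common_count`), read support is strict
#' (`fraction > sv_read_fraction_min`).
#'
#' @param cohort_af_max Maximum (exclusive) within-cohort allele frequency.
#' @param popdb_af_max Maximum (exclusive) population-database allele
#'   frequency.
#' @param splice_delta_min Minimum (exclusive) splice delta score.
#' @param sv_common_count SV clusters with at least this many database
#'   occurrences are considered common and excluded.
#' @param sv_read_fraction_min Minimum (exclusive) supporting-read fraction
#'   for an SV to be considered potentially causative.
#' @param sv_reciprocal_overlap_min Minimum reciprocal overlap for two SV
#'   calls of the same type to cluster, in (0, 1].
#' @param sv_ins_window Maximum start-position distance (bp) for insertion
#'   calls to cluster.
#' @param exclude_likely_benign Whether the splice screen drops
#'   likely-benign assertions alongside benign ones (conservative default
#'   `TRUE`; set `FALSE` for benign-only behaviour).
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(cohort_af_max = max_credible_af(disease_model()),
                             popdb_af_max = max_credible_af(disease_model()),
                             splice_delta_min = 0.5,
                             sv_common_count = 10L,
                             sv_read_fraction_min = 0.30,
                             sv_reciprocal_overlap_min = 0.8,
                             sv_ins_window = 50L,
                             exclude_likely_benign = TRUE) {
  num1 <- function(x, name, lo, hi) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
      stop_validation(name, " must be a single number in [", lo, ", ", hi, "]")
    }
    x
  }
  structure(
    list(
      cohort_af_max = num1(cohort_af_max, "cohort_af_max", 0, 1),
      popdb_af_max = num1(popdb_af_max, "popdb_af_max", 0, 1),
      splice_delta_min = num1(splice_delta_min, "splice_delta_min", 0, 1),
      sv_common_count = as.integer(num1(sv_common_count, "sv_common_count", 1, Inf)),
      sv_read_fraction_min = num1(sv_read_fraction_min, "sv_read_fraction_min", 0, 1),
      sv_reciprocal_overlap_min = num1(sv_reciprocal_overlap_min, "sv_reciprocal_overlap_min", 0, 1),
      sv_ins_window = as.integer(num1(sv_ins_window, "sv_ins_window", 0, Inf)),
      exclude_likely_benign = isTRUE(exclude_likely_benign)
    ),
    class = "threshold_config"
  )
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  for (nm in names(x)) cat("  ", nm, ": ", x[[nm]], "\n", sep = "")
  invisible(x)
}
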