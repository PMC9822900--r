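#' Sample QC step I: sex concordance
#'
#' Excludes every sample whose genotyping-called sex disagrees with the
#' assumed (enrollment) sex. Samples with `"unknown"` in either field are
#' retained by default: an unknown cannot certify a mismatch.
#'
#' @param samples sample table (see [sample_record()]).
#' @param exclude_unknown if `TRUE`, `"unknown"` in either field also
#'   excludes the sample.
#' @param cohort trace label for the cohort being filtered.
#' @return `list(samples = retained table, trace = one trace row)`.
#' @export
sex_mismatch_filter <- function(samples, exclude_unknown = FALSE,
                                cohort = "all") {
  unknown <- samples$assumed_sex == "unknown" | samples$called_sex == "unknown"
  mismatch <- samples$assumed_sex != samples$called_sex
  drop <- if (exclude_unknown) unknown | (mismatch & !unknown) else mismatch & !unknown
  list(
    samples = samples[!drop, , drop = FALSE],
    trace = trace_entry("I", cohort, "samples", nrow(samples),
                        samples$sample_id[drop])
  )
}

#' Sample QC step II: genotyping call rate
#'
#' Excludes samples with call rate strictly below the threshold; a sample at
#' exactly the threshold is retained.
#'
#' @param samples sample table.
#' @param threshold minimum acceptable call rate, in `(0, 1]`; default 0.98.
#' @param cohort trace label.
#' @return `list(samples, trace)` as in [sex_mismatch_filter()].
#' @export
call_rate_filter <- function(samples, threshold = 0.98, cohort = "all") {
  stopifnot(threshold > 0, threshold <= 1)
  drop <- samples$call_rate < threshold
  list(
    samples = samples[!drop, , drop = FALSE],
    trace = trace_entry("II", cohort, "samples", nrow(samples),
                        samples$sample_id[drop])
  )
}

#' Sample QC step III: CNV-count outliers
#'
#' Computes the number of CNV calls per sample (samples without calls count
#' zero), the mean and the sample (n-1) standard deviation of those counts
#' over the input samples, and excludes every sample whose count strictly
#' exceeds `mean + sd_multiplier * sd`. The trim is one-sided: an excess of
#' calls flags a failed array, a deficit does not. Note this step is not
#' idempotent -- removing the outliers changes the mean and SD of the
#' survivors.
#'
#' @param samples sample table (should already have passed steps I-II).
#' @param calls CNV call table for these samples.
#' @param sd_multiplier number of SDs above the mean tolerated; default 2.
#' @param cohort trace label.
#' @return `list(samples, trace)`.
#' @export
cnv_count_outlier_filter <- function(samples, calls, sd_multiplier = 2,
                                     cohort = "all") {
  if (nrow(samples) < 2) {
    stop("need at least 2 samples to estimate the CNV-count standard deviation")
  }
  counts <- tabulate(factor(calls$sample_id, levels = samples$sample_id),
                     nbins = nrow(samples))
  cutoff <- mean(counts) + sd_multiplier * stats::sd(counts)
  drop <- counts > cutoff
  list(
    samples = samples[!drop, , drop = FALSE],
    trace = trace_entry("III", cohort, "samples", nrow(samples),
                        samples$sample_id[drop])
  )
}
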