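#' Per-step accounting of the filter cascade
#'
#' Every QC and filter step reports one trace row: what went in, what came
#' out, and exactly which samples or calls were dropped. The conservation
#' identity `n_in == n_out + n_excluded` holds at every row by construction
#' and is re-checked by [validate_trace()].
#'
#' @param step_id cascade step label (`"I"` .. `"IX"`).
#' @param cohort `"cases"`, `"controls"` or `"all"`.
#' @param unit `"samples"` or `"cnvs"`.
#' @param n_in number of units entering the step.
#' @param excluded_ids character vector of dropped identifiers.
#' @return one-row data.frame; `excluded_ids` is a list column.
#' @export
trace_entry <- function(step_id, cohort, unit, n_in, excluded_ids) {
  excluded_ids <- as.character(excluded_ids)
  stopifnot(unit %in% c("samples", "cnvs"),
            cohort %in% c("cases", "controls", "all"),
            n_in >= length(excluded_ids))
  data.frame(step_id = step_id, cohort = cohort, unit = unit,
             n_in = as.integer(n_in),
             n_out = as.integer(n_in - length(excluded_ids)),
             n_excluded = length(excluded_ids),
             excluded_ids = I(list(excluded_ids)),
             stringsAsFactors = FALSE)
}

#' Validate a filter trace
#'
#' Asserts the conservation identity at every row and the column contract.
#'
#' @param trace data.frame of [trace_entry()] rows.
#' @return `trace`, invisibly; errors if any row violates conservation.
#' @export
validate_trace <- function(trace) {
  needed <- c("step_id", "cohort", "unit", "n_in", "n_out", "n_excluded", "excluded_ids")
  if (!all(needed %in% names(trace))) stop("trace is missing required columns")
  n_listed <- vapply(trace$excluded_ids, length, integer(1))
  if (!all(trace$n_excluded == n_listed)) {
    stop("trace row lists a different number of excluded ids than n_excluded")
  }
  if (!all(trace$n_in == trace$n_out + trace$n_excluded)) {
    stop("conservation violated: n_in != n_out + n_excluded")
  }
  invisible(trace)
}

#' Write a filter trace as TSV
#'
#' The `excluded_ids` list column is flattened to a comma-separated string.
#'
#' @param trace trace data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  flat <- trace
  flat$excluded_ids <- vapply(trace$excluded_ids, paste, character(1), collapse = ",")
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
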