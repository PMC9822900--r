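# Independent oracles and small random-instance generators shared by the
# suite. The oracles deliberately avoid the package's interval machinery:
# overlap is checked pair by pair with the textbook inequality.

# O(n * m) all-pairs overlap: which rows of `query` are overlapped by at
# least one row of `subject`?
brute_force_overlapped <- function(query, subject, type_matched = FALSE) {
  vapply(seq_len(nrow(query)), function(i) {
    hit <- FALSE
    for (j in seq_len(nrow(subject))) {
      if (type_matched && query$cnv_type[i] != subject$cnv_type[j]) next
      if (query$chrom[i] == subject$chrom[j] &&
          query$start[i] <= subject$end[j] &&
          subject$start[j] <= query$end[i]) {
        hit <- TRUE
        break
      }
    }
    hit
  }, logical(1))
}

# Random CNV call table on a small genome, for oracle-equivalence tests.
random_calls <- function(n, prefix = "s", n_chrom = 4, span = 1e5) {
  if (n == 0) return(empty_calls())
  start <- sample.int(span, n, replace = TRUE)
  cnv_call(
    sample_id = paste0(prefix, sample.int(max(1, n %/% 3), n, replace = TRUE)),
    chrom = as.character(sample.int(n_chrom, n, replace = TRUE)),
    start = start,
    end = start + sample.int(2e4, n, replace = TRUE) - 1,
    copy_state = sample(c(0L, 1L, 3L, 4L), n, replace = TRUE),
    num_snps = sample.int(50, n, replace = TRUE),
    conf = round(runif(n, 0, 100), 1)
  )
}

# Shared fixture objects (built once per test run).
fixture <- arm_cohort_fixture()
fixture_prioritized <- local({
  res <- run_cascade(fixture$samples, fixture$calls, fixture$control_calls,
                     fixture$tracks)
  prioritize_calls(res$calls, fixture$tracks, fixture$samples,
                   fixture$n_controls)
})
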