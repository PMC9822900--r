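#!/usr/bin/env Rscript
# Simulate a case-control SNP-array cohort with spike-in ground truth and
# write it in the external formats the cascade consumes (PennCNV rawcnv,
# sample-metadata TSV, BED annotation tracks). Downstream drivers re-read
# these files, exercising the full IO boundary.

suppressPackageStartupMessages(library(cnvcascade))

dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(n_cases = 100, n_controls = 200, seed = 20260927,
                     spike_specs = spike_specs(20))
cohort <- generate_cohort(cfg)
tracks <- generate_tracks(cfg)

write_penncnv(cohort$case_calls, "results/simulated/cases.rawcnv")
write_penncnv(cohort$control_calls, "results/simulated/controls.rawcnv")
write_samples(cohort$samples, "results/simulated/samples.tsv")
write.table(cohort$truth, "results/simulated/spike_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# Tracks go out as BED (0-based half-open), converting at the boundary.
as_bed <- function(f) data.frame(chrom = paste0("chr", f$chrom),
                                 start = f$start - 1, end = f$end,
                                 name = f$name, score = 0, strand = f$strand)
for (cls in unique(tracks$feature_class)) {
  sub <- tracks[tracks$feature_class == cls, ]
  write.table(as_bed(sub), sprintf("results/simulated/%s.bed", cls),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

cat(sprintf(
  "Simulated %d cases (%d calls) and %d controls (%d calls); %d spikes planted;\n%d genes, %d population features written under results/simulated/.\n",
  cfg$n_cases, nrow(cohort$case_calls), cfg$n_controls,
  nrow(cohort$control_calls), nrow(cohort$truth),
  sum(tracks$feature_class == "coding_gene"),
  sum(tracks$feature_class %in% c("pop_loss", "pop_gain"))))
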