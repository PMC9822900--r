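#!/usr/bin/env Rscript
# Simulate comparative-Ct (delta-delta-Ct) qPCR confirmation of the reference
# cohort's submicroscopic events in their trios, plus a noise sweep showing
# how Ct noise propagates into integer copy-number calls.

suppressPackageStartupMessages(library(cnvcascade))

dir.create("results", showWarnings = FALSE)

fx <- arm_cohort_fixture()
sub <- fx$calls[!fx$calls$terminal, ]

obs_to_cn <- function(obs, type) {
  if (obs == "present") {
    if (type == "loss") 1L else 3L
  } else 2L  # absent or missing parents are simulated diploid
}

rows <- lapply(seq_len(nrow(sub)), function(i) {
  call <- sub[i, ]
  cn <- c(child = if (call$cnv_type == "loss") 1L else 3L)
  ids <- c(child = call$sample_id, mother = NA, father = NA)
  if (call$mother_obs != "missing") {
    cn["mother"] <- obs_to_cn(call$mother_obs, call$cnv_type)
    ids["mother"] <- "mother"
  }
  if (call$father_obs != "missing") {
    cn["father"] <- obs_to_cn(call$father_obs, call$cnv_type)
    ids["father"] <- "father"
  }
  names(cn)[1] <- call$sample_id
  plate <- generate_qpcr_plate(call$locus, cn, noise_sd = 0.15,
                               replicates = 3, seed = 4200 + i)
  est <- quantify_plate(plate)
  conf <- confirm_cnv(est, call$cnv_type, call$sample_id,
                      ids[["mother"]], ids[["father"]])
  data.frame(sample_id = call$sample_id, locus = call$locus,
             predicted = call$cnv_type, child_cn = conf$child_cn,
             confirmed = conf$confirmed, inheritance = conf$inheritance,
             stringsAsFactors = FALSE)
})
confirmation <- do.call(rbind, rows)
write.table(confirmation, "results/qpcr_confirmation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Trio qPCR confirmation of the submicroscopic events:\n")
print(confirmation, row.names = FALSE)

cat("\nCopy-number call accuracy vs Ct noise (200 trios per level, 3 replicates):\n")
truths <- list(c(child = 1L, mother = 1L, father = 2L),
               c(child = 3L, mother = 2L, father = 3L),
               c(child = 1L, mother = 2L, father = 2L))
for (noise in c(0.05, 0.1, 0.15, 0.25, 0.4)) {
  called <- correct <- 0L
  for (i in 1:200) {
    truth <- truths[[(i - 1L) %% 3L + 1L]]
    est <- quantify_plate(generate_qpcr_plate("L", truth, noise_sd = noise,
                                              replicates = 3, seed = 7000 + i))
    cn <- est$cn_call[match(names(truth), est$sample_id)]
    called <- called + sum(!is.na(cn))
    correct <- correct + sum(!is.na(cn) & cn == truth)
  }
  cat(sprintf("  noise_sd = %.2f Ct: %5.1f%% correct among %d/600 called\n",
              noise, 100 * correct / called, called))
}
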