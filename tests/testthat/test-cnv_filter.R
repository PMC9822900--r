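test_that("confidence gate is strict-below 30 and drops scoreless calls", {
  calls <- cnv_call(c("a", "b", "c"), "1", c(100, 200, 300), c(150, 250, 350),
                    1, 5, conf = c(29.99, 30, NA))
  res <- confidence_filter(calls)
  expect_equal(res$calls$sample_id, "b")
  expect_equal(res$trace$n_excluded, 2L)
})

test_that("SNP-support gate is strict-below 3", {
  calls <- cnv_call(c("a", "b", "c"), "1", c(100, 200, 300), c(150, 250, 350),
                    1, num_snps = c(2, 3, 150), conf = 50)
  res <- snp_count_filter(calls)
  expect_equal(res$calls$num_snps, c(3L, 150L))
})

test_that("interval overlap follows 1-based inclusive semantics", {
  expect_true(interval_overlaps("1", 100, 200, "1", 200, 300))   # one shared base
  expect_false(interval_overlaps("1", 100, 200, "1", 201, 300))  # adjacent
  expect_false(interval_overlaps("1", 100, 200, "2", 100, 200))  # other chrom
  expect_true(interval_overlaps("chr1", 5, 5, "1", 1, 10))       # prefix stripped
})

test_that("control overlap excludes on any type and any shared base by default", {
  case <- cnv_call("p1", "1", 100, 200, 1, 10, 50)
  ctrl_gain <- cnv_call("c1", "1", 150, 160, 3, 10, 50)
  res <- control_overlap_filter(case, ctrl_gain)
  expect_equal(nrow(res$calls), 0)
  # type-matched variant retains the cross-type case
  res_tm <- control_overlap_filter(case, ctrl_gain, type_matched = TRUE)
  expect_equal(nrow(res_tm$calls), 1)
  # no controls on the chromosome: retained
  res_none <- control_overlap_filter(case, cnv_call("c2", "2", 100, 200, 1, 10, 50))
  expect_equal(nrow(res_none$calls), 1)
})

test_that("reciprocal-overlap variant requires the fraction on both intervals", {
  case <- cnv_call("p1", "1", 1000, 1999, 1, 10, 50)      # 1 kb
  ctrl <- cnv_call("c1", "1", 1900, 2899, 1, 10, 50)      # 1 kb, 100 bp shared
  expect_equal(nrow(control_overlap_filter(case, ctrl)$calls), 0)
  expect_equal(nrow(control_overlap_filter(case, ctrl, min_reciprocal = 0.5)$calls), 1)
  expect_equal(nrow(control_overlap_filter(case, ctrl, min_reciprocal = 0.1)$calls), 0)
})

test_that("interval-join filtering equals the brute-force all-pairs oracle", {
  set.seed(2024)
  for (rep in 1:100) {
    cases <- random_calls(sample.int(50, 1), "p")
    ctrls <- random_calls(sample.int(200, 1), "c")
    res <- control_overlap_filter(cases, ctrls)
    oracle_keep <- !brute_force_overlapped(cases, ctrls)
    expect_identical(call_uid(res$calls), call_uid(cases)[oracle_keep])
    tm <- control_overlap_filter(cases, ctrls, type_matched = TRUE)
    oracle_tm <- !brute_force_overlapped(cases, ctrls, type_matched = TRUE)
    expect_identical(call_uid(tm$calls), call_uid(cases)[oracle_tm])
  }
})

test_that("population-variant filter is type-matched", {
  pop <- rbind(annotation_feature("1", 100, 200, "pop_loss", "L"),
               annotation_feature("1", 300, 400, "pop_gain", "G"))
  loss_on_loss <- cnv_call("a", "1", 150, 180, 1, 5, 50)
  loss_on_gain <- cnv_call("b", "1", 350, 380, 1, 5, 50)
  gain_on_gain <- cnv_call("c", "1", 350, 380, 3, 5, 50)
  res <- population_variant_filter(rbind(loss_on_loss, loss_on_gain, gain_on_gain), pop)
  expect_equal(res$calls$sample_id, "b")
})

test_that("promoters derive strand-aware, clipped at base 1", {
  genes <- rbind(annotation_feature("1", 10000, 12000, "coding_gene", "P", "+"),
                 annotation_feature("1", 50000, 52000, "coding_gene", "M", "-"),
                 annotation_feature("2", 500, 900, "coding_gene", "E", "+"))
  pr <- derive_promoters(genes, 2000)
  expect_equal(pr$start[pr$name == "P"], 8000)
  expect_equal(pr$end[pr$name == "P"], 9999)
  expect_equal(pr$start[pr$name == "M"], 52001)
  expect_equal(pr$end[pr$name == "M"], 54000)
  expect_equal(pr$start[pr$name == "E"], 1)  # clipped
  expect_error(derive_promoters(annotation_feature("1", 10, 20, "coding_gene", "X", ".")),
               "strand")
})

test_that("genic residency keeps calls in gene bodies or derived promoters", {
  genes <- annotation_feature("1", 10000, 12000, "coding_gene", "P", "+")
  body <- cnv_call("a", "1", 11000, 11500, 1, 5, 50)
  upstream1 <- cnv_call("b", "1", 9999, 9999, 1, 5, 50)   # 1 bp upstream of TSS
  far <- cnv_call("c", "1", 100, 200, 1, 5, 50)
  res <- genic_filter(rbind(body, upstream1, far), genes)
  expect_equal(res$calls$sample_id, c("a", "b"))
  # explicit promoter features are honored instead of derivation
  explicit <- rbind(genes, annotation_feature("1", 100, 200, "promoter", "P"))
  res2 <- genic_filter(rbind(body, upstream1, far), explicit)
  expect_equal(res2$calls$sample_id, c("a", "c"))
})

test_that("cascade on empty inputs yields empty output and zero-count trace", {
  res <- run_cascade(sample_record(character(0)), empty_calls(), empty_calls(),
                     empty_features())
  expect_equal(nrow(res$calls), 0)
  expect_true(all(res$trace$n_in == 0))
  expect_silent(validate_trace(res$trace))
})

test_that("clean spikes survive the cascade at 100%", {
  cfg <- cohort_config(n_cases = 40, n_controls = 80, seed = 101,
                       spike_specs = spike_specs(20))
  g <- generate_cohort(cfg)
  res <- run_cascade(g$samples, g$case_calls, g$control_calls,
                     generate_tracks(cfg))
  key <- function(d) paste(d$chrom, d$start, d$end)
  expect_true(all(key(g$truth) %in% key(res$calls)))
})

test_that("control-planted and catalogue-covered spikes die exactly at VI and VII", {
  sp <- rbind(spike_specs(4, in_controls = TRUE),
              spike_specs(8, in_pop_track = TRUE)[5:8, ])
  cfg <- cohort_config(n_cases = 30, n_controls = 60, seed = 202,
                       spike_specs = sp)
  g <- generate_cohort(cfg)
  tracks <- generate_tracks(cfg)
  step_of_death <- function(spike_row) {
    calls <- g$case_calls
    key <- paste(calls$chrom, calls$start, calls$end)
    target <- paste(spike_row$chrom, spike_row$start, spike_row$end)
    present <- function(cc) target %in% paste(cc$chrom, cc$start, cc$end)
    f4 <- confidence_filter(calls); stopifnot(present(f4$calls))
    f5 <- snp_count_filter(f4$calls); stopifnot(present(f5$calls))
    ctrl <- snp_count_filter(confidence_filter(g$control_calls)$calls)$calls
    f6 <- control_overlap_filter(f5$calls, ctrl)
    if (!present(f6$calls)) return("VI")
    f7 <- population_variant_filter(f6$calls, tracks)
    if (!present(f7$calls)) return("VII")
    f8 <- genic_filter(f7$calls, tracks)
    if (!present(f8$calls)) return("VIII")
    "survived"
  }
  deaths <- vapply(seq_len(nrow(g$truth)), function(i) step_of_death(g$truth[i, ]),
                   character(1))
  expect_equal(deaths, c(rep("VI", 4), rep("VII", 4)))
})

test_that("non-genic spikes die exactly at the residency step", {
  cfg <- cohort_config(n_cases = 20, n_controls = 40, seed = 303,
                       spike_specs = spike_specs(5, genic = FALSE))
  g <- generate_cohort(cfg)
  tracks <- generate_tracks(cfg)
  res <- run_cascade(g$samples, g$case_calls, g$control_calls, tracks)
  key <- function(d) paste(d$chrom, d$start, d$end)
  expect_false(any(key(g$truth) %in% key(res$calls)))
  viii <- res$trace[res$trace$step_id == "VIII", ]
  dropped <- unlist(viii$excluded_ids)
  expect_true(all(vapply(seq_len(nrow(g$truth)), function(i) {
    any(grepl(paste0(g$truth$chrom[i], ":", g$truth$start[i], "-", g$truth$end[i]),
              dropped, fixed = TRUE))
  }, logical(1))))
})

test_that("each step is monotone and permutation-invariant on the retained set", {
  set.seed(77)
  cases <- random_calls(40, "p")
  ctrls <- random_calls(120, "c")
  res <- control_overlap_filter(cases, ctrls)
  expect_true(nrow(res$calls) <= nrow(cases))
  perm <- sample(nrow(cases))
  res_perm <- control_overlap_filter(cases[perm, ], ctrls)
  key <- function(d) sort(paste(d$sample_id, d$chrom, d$start, d$end))
  expect_equal(key(res_perm$calls), key(res$calls))
})

test_that("applying VII then VIII equals VIII then VII (independent exclusions)", {
  set.seed(88)
  calls <- random_calls(60, "p")
  pop <- annotation_feature(as.character(sample.int(4, 20, TRUE)),
                            s <- sample.int(1e5, 20, TRUE), s + 5000,
                            sample(c("pop_loss", "pop_gain"), 20, TRUE), "pv")
  genes <- annotation_feature(as.character(sample.int(4, 15, TRUE)),
                              s2 <- sample.int(1e5, 15, TRUE), s2 + 8000,
                              "coding_gene", paste0("g", 1:15), "+")
  a <- genic_filter(population_variant_filter(calls, pop)$calls, genes)$calls
  b <- population_variant_filter(genic_filter(calls, genes)$calls, pop)$calls
  key <- function(d) sort(paste(d$sample_id, d$chrom, d$start, d$end))
  expect_equal(key(a), key(b))
})

test_that("visual-inspection flags are honored as the final pass-through step", {
  fx <- arm_cohort_fixture()
  fx$calls$visual_inspection_pass <- TRUE
  fx$calls$visual_inspection_pass[3] <- FALSE
  res <- run_cascade(fx$samples, fx$calls, fx$control_calls, fx$tracks)
  expect_equal(nrow(res$calls), 13)
  ix <- res$trace[res$trace$step_id == "IX", ]
  expect_equal(ix$n_excluded, 1L)
})
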