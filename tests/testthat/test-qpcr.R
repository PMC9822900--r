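plate_row <- function(sample_id, gene, ct, locus = "L") {
  data.frame(sample_id = sample_id, locus = locus, gene = gene,
             replicate = seq_along(ct), ct = ct, stringsAsFactors = FALSE)
}

manual_plate <- function(target, cftr, bnc1, rna, id = "s") {
  rbind(plate_row(id, "target", target), plate_row(id, "CFTR", cftr),
        plate_row(id, "BNC1", bnc1), plate_row(id, "RNA", rna))
}

test_that("delta Ct averages per housekeeping gene first, then across genes", {
  expect_equal(delta_ct(manual_plate(25, 24, 24, 24)), 1.0)
  expect_equal(delta_ct(manual_plate(24, 24, 24, 24)), 0.0)
  # unequal replicate counts: per-gene means 23, 24, 25 -> reference 24
  expect_equal(delta_ct(manual_plate(26, c(22, 24), 24, 25)), 2.0)
  expect_error(delta_ct(manual_plate(25, 24, 24, 24)[1:3, ]), "missing")  # no RNA rows
  # target never amplified -> +Inf sentinel
  expect_equal(delta_ct(manual_plate(c(Inf, Inf), 24, 24, 24)), Inf)
})

test_that("relative quantity is 2^(-ddct)", {
  expect_equal(delta_delta_ct(1, 1)$rq, 1.0)
  expect_equal(delta_delta_ct(2, 1)$rq, 0.5)
  expect_equal(delta_delta_ct(1 - 0.584962500721156, 1)$rq, 1.5)
})

test_that("copy-number bins are centered on theoretical doses with no-call guards", {
  expect_equal(call_copy_number(c(1.0, 0.5, 1.5, 0.1, 2.5)),
               c(2L, 1L, 3L, 0L, 4L))
  expect_true(is.na(call_copy_number(0.76)))   # within 0.05 of the 0.75 edge
  expect_true(is.na(call_copy_number(1.21)))
  expect_equal(call_copy_number(0.9), 2L)
  expect_error(call_copy_number(-0.1), ">= 0")
  # monotone non-decreasing in RQ away from guard bands
  rq <- c(0.05, 0.4, 1.0, 1.6, 2.2)
  expect_false(is.unsorted(call_copy_number(rq)))
})

test_that("noiseless simulated plates recover the true copy number exactly", {
  for (cn in c(1L, 2L, 3L)) {
    plate <- generate_qpcr_plate("L", c(child = cn), noise_sd = 0, seed = 1)
    est <- quantify_plate(plate)
    expect_equal(est$cn_call, cn, info = paste("true CN", cn))
    expect_equal(est$relative_quantity, cn / 2)
  }
  # CN1: target exactly one cycle later than the calibrator's
  plate <- generate_qpcr_plate("L", c(child = 1L), noise_sd = 0, seed = 1)
  tgt <- function(id) mean(plate$ct[plate$sample_id == id & plate$gene == "target"])
  expect_equal(tgt("child") - tgt("calibrator"), 1.0)
  # CN0 never amplifies and is called CN0
  plate0 <- generate_qpcr_plate("L", c(child = 0L), noise_sd = 0, seed = 1)
  expect_true(all(is.infinite(plate0$ct[plate0$sample_id == "child" &
                                          plate0$gene == "target"])))
  expect_equal(quantify_plate(plate0)$cn_call, 0L)
})

test_that("confirmation requires deviation in the predicted direction", {
  est <- data.frame(sample_id = c("ch", "mo", "fa"), locus = "L",
                    delta_ct = 0, delta_delta_ct = 0,
                    relative_quantity = c(0.5, 0.5, 1),
                    cn_call = c(1L, 1L, 2L), stringsAsFactors = FALSE)
  res <- confirm_cnv(est, "loss", "ch", "mo", "fa")
  expect_true(res$confirmed)
  expect_equal(res$inheritance, "maternal")
  # de novo: both parents diploid
  est$cn_call <- c(1L, 2L, 2L)
  expect_equal(confirm_cnv(est, "loss", "ch", "mo", "fa")$inheritance, "de_novo")
  # child at CN2: unconfirmed
  est$cn_call <- c(2L, 2L, 2L)
  expect_false(confirm_cnv(est, "loss", "ch", "mo", "fa")$confirmed)
  # child no-call: unconfirmed with reason
  est$cn_call <- c(NA, 2L, 2L)
  res_nc <- confirm_cnv(est, "loss", "ch", "mo", "fa")
  expect_false(res_nc$confirmed)
  expect_equal(res_nc$reason, "child_no_call")
  # gain deviating downward does not confirm
  est$cn_call <- c(1L, 2L, 2L)
  expect_false(confirm_cnv(est, "gain", "ch", "mo", "fa")$confirmed)
  # unassayed parents -> unknown
  est$cn_call <- c(1L, 2L, 2L)
  expect_equal(confirm_cnv(est, "loss", "ch")$inheritance, "unknown")
})

test_that("noisy trios recover >= 95% of copy numbers and matching inheritance", {
  truths <- list(
    maternal = c(child = 1L, mother = 1L, father = 2L),
    paternal = c(child = 3L, mother = 2L, father = 3L),
    de_novo = c(child = 1L, mother = 2L, father = 2L)
  )
  n_trios <- 200
  correct_cn <- 0L
  called_cn <- 0L
  inh_checked <- 0L
  inh_correct <- 0L
  for (i in seq_len(n_trios)) {
    truth_name <- names(truths)[(i - 1L) %% 3L + 1L]
    truth <- truths[[truth_name]]
    plate <- generate_qpcr_plate("L", truth, noise_sd = 0.15, replicates = 3,
                                 seed = 5000 + i)
    est <- quantify_plate(plate)
    called <- est$cn_call[match(names(truth), est$sample_id)]
    called_cn <- called_cn + sum(!is.na(called))
    correct_cn <- correct_cn + sum(!is.na(called) & called == truth)
    if (!anyNA(called) && all(called == truth)) {
      res <- confirm_cnv(est, if (truth[["child"]] < 2) "loss" else "gain",
                         "child", "mother", "father")
      inh_checked <- inh_checked + 1L
      inh_correct <- inh_correct + as.integer(identical(res$inheritance, truth_name))
    }
  }
  # accuracy is measured among made calls; a guard-band no-call is abstention
  expect_gte(correct_cn / called_cn, 0.95)
  expect_gte(called_cn / (3L * n_trios), 0.8)  # abstention stays rare
  # labels match simulation truth whenever the trio is fully and correctly called
  expect_equal(inh_correct, inh_checked)
  expect_gt(inh_checked, 150)
})
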