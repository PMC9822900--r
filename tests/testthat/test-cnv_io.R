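test_that("rawcnv lines parse with verbatim 1-based inclusive coordinates", {
  f <- withr::local_tempfile()
  writeLines(paste(
    "chr2:72623204-72939279 numsnp=150 length=316076 state2,cn=1 caseA",
    "startsnp=rsA endsnp=rsB conf=45.1"), f)
  calls <- read_penncnv(f)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$chrom, "2")
  expect_equal(calls$start, 72623204)
  expect_equal(calls$end, 72939279)
  expect_equal(calls$copy_state, 1L)
  expect_equal(calls$cnv_type, "loss")
  expect_equal(calls$num_snps, 150L)
  expect_equal(calls$conf, 45.1)
  expect_equal(calls$sample_id, "caseA")
  expect_equal(calls$start_snp, "rsA")
  expect_equal(calls$end_snp, "rsB")
})

test_that("rawcnv parsing handles optional fields, extras and edge lines", {
  f <- withr::local_tempfile()
  writeLines(c(
    "chr1:100-200 numsnp=5 state5,cn=3 sampleX",
    "chrX:10-20 numsnp=3 length=11 state1,cn=0 sampleY foo=bar conf=31"
  ), f)
  calls <- read_penncnv(f)
  expect_equal(nrow(calls), 2)
  expect_true(is.na(calls$conf[1]))
  expect_equal(calls$extra[2], "foo=bar")
  expect_equal(calls$chrom[2], "X")
  expect_equal(calls$cnv_type, c("gain", "loss"))

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_equal(nrow(read_penncnv(empty)), 0)
})

test_that("copy-neutral and malformed lines are rejected with the line number", {
  f <- withr::local_tempfile()
  writeLines(c("chr1:100-200 numsnp=5 state3,cn=2 s1"), f)
  expect_error(read_penncnv(f), "line 1.*cn=2")
  writeLines(c("chr1:100-200 numsnp=5 state2,cn=1 ok",
               "chr99:1-2 numsnp=3 state2,cn=1 s2"), f)
  expect_error(read_penncnv(f), "line 2")
  writeLines("not-a-region numsnp=3 state2,cn=1 s", f)
  expect_error(read_penncnv(f), "malformed region")
})

test_that("rawcnv write/read round-trips every field, preserving order and count", {
  set.seed(42)
  calls <- random_calls(25)
  calls$start_snp[1:5] <- paste0("rs", 1:5)
  calls$extra[3] <- "k1=v1 k2=v2"
  f <- withr::local_tempfile()
  write_penncnv(calls, f)
  back <- read_penncnv(f)
  rownames(calls) <- rownames(back) <- NULL
  expect_equal(back, calls)
})

test_that("BED records convert to 1-based inclusive at the boundary", {
  f <- withr::local_tempfile()
  writeLines(c("chr7\t99\t200\tG1\t0\t+",
               "chr7\t0\t1\tG2\t0\t-",
               "chr8\t10\t30\tG3\t0\t+"), f)
  feats <- read_bed_track(f, "coding_gene")
  expect_equal(nrow(feats), 3)
  expect_equal(feats$start, c(100, 1, 11))
  expect_equal(feats$end, c(200, 1, 30))
  expect_equal(feats$name, c("G1", "G2", "G3"))
  expect_equal(feats$strand, c("+", "-", "+"))
  # internal length equals BED end - start for every record
  bed_len <- c(200 - 99, 1 - 0, 30 - 10)
  expect_equal(feats$end - feats$start + 1, bed_len)
})

test_that("degenerate BED intervals are rejected", {
  f <- withr::local_tempfile()
  writeLines("chr1\t100\t100", f)
  expect_error(read_bed_track(f, "pop_loss"), "end <= start")
})

test_that("printed locus strings with grouped digits parse", {
  iv <- parse_locus_string("Chr2:72.623.204-72.939.279")
  expect_equal(iv$chrom, "2")
  expect_equal(iv$start, 72623204)
  expect_equal(iv$end, 72939279)
  expect_error(parse_locus_string("2:abc-def"), "malformed")
})

test_that("report writing is deterministic and round-trips", {
  f <- withr::local_tempfile()
  write_report(fixture_prioritized, f)
  lines <- readLines(f)
  expect_equal(length(lines), 13 + 1)  # 13 events plus header
  back <- read_report(f)
  expect_equal(back$locus, fixture_prioritized$locus)
  expect_equal(back$size_bp, fixture_prioritized$size_bp)
  expect_equal(unclass(back$genes), unclass(fixture_prioritized$genes),
               ignore_attr = TRUE)
  expect_equal(unclass(back$sample_id), unclass(fixture_prioritized$sample_id),
               ignore_attr = TRUE)

  empty <- fixture_prioritized[0, ]
  write_report(empty, f)
  expect_equal(length(readLines(f)), 1)
})

test_that("sample metadata and qPCR tables round-trip through disk", {
  f <- withr::local_tempfile()
  write_samples(fixture$samples, f)
  back <- read_samples(f)
  rownames(back) <- NULL
  expect_equal(back, fixture$samples)

  plate <- generate_qpcr_plate("del2p13.2", c(child = 1), noise_sd = 0.1, seed = 5)
  g <- withr::local_tempfile()
  write_qpcr(plate, g)
  back <- read_qpcr(g)
  expect_equal(back$ct, plate$ct, tolerance = 1e-12)
  expect_equal(back$gene, plate$gene)
})
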