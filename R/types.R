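#' @importFrom stats rnorm rnbinom runif sd setNames
#' @importFrom utils read.delim write.table
NULL

.CHROMS <- c(as.character(1:22), "X", "Y")

#' Construct a table of genomic intervals
#'
#' Coordinates are 1-based and inclusive on both ends throughout the package:
#' a single base is `start == end` and the length of an interval is
#' `end - start + 1`. Chromosomes use hg19 naming without the `chr` prefix
#' (`"1"`..`"22"`, `"X"`, `"Y"`); a `chr` prefix on input is stripped.
#'
#' @param chrom character vector of chromosome labels.
#' @param start,end integer-like base positions, 1-based inclusive.
#' @return a data.frame with columns `chrom`, `start`, `end`.
#' @export
genomic_interval <- function(chrom, start, end) {
  chrom <- normalize_chrom(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(chrom)) || any(is.na(start)) || any(is.na(end))) {
    stop("interval fields must not be missing")
  }
  if (any(start < 1)) stop("interval start must be >= 1")
  if (any(start > end)) stop("interval start must be <= end")
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Normalize chromosome labels
#'
#' Strips a leading `chr`/`Chr` prefix and validates against the hg19
#' chromosome set.
#'
#' @param chrom character vector.
#' @return character vector of bare labels.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  bad <- !(chrom %in% .CHROMS)
  if (any(bad)) {
    stop("unknown chromosome label(s): ", paste(unique(chrom[bad]), collapse = ", "))
  }
  chrom
}

#' Construct a table of CNV calls
#'
#' One row per call in the dialect of SNP-array HMM callers: an interval, the
#' integer copy state (never 2 -- a copy-neutral segment is not a CNV), the
#' number of consecutive called SNPs supporting the call, and a confidence
#' score in log Bayes factor units (may be `NA` when the caller did not emit
#' one). `cnv_type` is derived: copy state below 2 is a `loss`, above 2 a
#' `gain`.
#'
#' @param sample_id character vector of sample identifiers.
#' @param chrom,start,end interval fields (see [genomic_interval()]).
#' @param copy_state integer copy number in `{0, 1, 3, 4}`.
#' @param num_snps positive integer count of consecutive called SNPs.
#' @param conf numeric confidence (log Bayes factor); `NA` if absent.
#' @param start_snp,end_snp optional SNP identifiers at the breakpoint probes.
#' @param extra optional character vector of opaque `key=value` tokens
#'   preserved from the source file (`""` if none).
#' @return a data.frame of class-free CNV calls with columns `sample_id`,
#'   `chrom`, `start`, `end`, `copy_state`, `cnv_type`, `num_snps`, `conf`,
#'   `start_snp`, `end_snp`, `extra`.
#' @export
cnv_call <- function(sample_id, chrom, start, end, copy_state, num_snps,
                     conf = NA_real_, start_snp = NA_character_,
                     end_snp = NA_character_, extra = "") {
  iv <- genomic_interval(chrom, start, end)
  n <- nrow(iv)
  copy_state <- as.integer(copy_state)
  if (any(is.na(copy_state)) || any(!copy_state %in% c(0L, 1L, 3L, 4L))) {
    stop("copy_state must be one of 0, 1, 3, 4 (copy-neutral segments are not CNVs)")
  }
  num_snps <- as.integer(num_snps)
  if (any(is.na(num_snps)) || any(num_snps < 1L)) stop("num_snps must be >= 1")
  df <- data.frame(
    sample_id = rep_len(as.character(sample_id), n),
    iv,
    copy_state = rep_len(copy_state, n),
    cnv_type = ifelse(rep_len(copy_state, n) < 2L, "loss", "gain"),
    num_snps = rep_len(num_snps, n),
    conf = rep_len(as.numeric(conf), n),
    start_snp = rep_len(as.character(start_snp), n),
    end_snp = rep_len(as.character(end_snp), n),
    extra = rep_len(as.character(extra), n),
    stringsAsFactors = FALSE
  )
  df
}

#' An empty CNV call table
#' @return zero-row data.frame with the [cnv_call()] columns.
#' @export
empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(), start = numeric(),
             end = numeric(), copy_state = integer(), cnv_type = character(),
             num_snps = integer(), conf = numeric(), start_snp = character(),
             end_snp = character(), extra = character(),
             stringsAsFactors = FALSE)
}

#' Construct a table of per-sample QC records
#'
#' @param sample_id character identifiers.
#' @param assumed_sex,called_sex `"male"`, `"female"` or `"unknown"`; the
#'   assumed sex comes from enrollment records, the called sex from the
#'   genotyping platform.
#' @param call_rate fraction of array SNPs successfully genotyped, in `[0, 1]`.
#' @param cohort `"case"` or `"control"`.
#' @param mother_id,father_id optional sample ids of the parents (`NA` if not
#'   enrolled); must differ from `sample_id`.
#' @param visual_inspection_pass optional logical flag supplied by an external
#'   manual review of the intensity plots; defaults to `TRUE`.
#' @return a data.frame with one row per sample.
#' @export
sample_record <- function(sample_id, assumed_sex = "unknown",
                          called_sex = "unknown", call_rate = 1,
                          cohort = "case", mother_id = NA_character_,
                          father_id = NA_character_,
                          visual_inspection_pass = TRUE) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  sexes <- c("male", "female", "unknown")
  assumed_sex <- rep_len(as.character(assumed_sex), n)
  called_sex <- rep_len(as.character(called_sex), n)
  if (!all(assumed_sex %in% sexes) || !all(called_sex %in% sexes)) {
    stop("sex must be 'male', 'female' or 'unknown'")
  }
  call_rate <- rep_len(as.numeric(call_rate), n)
  if (any(is.na(call_rate)) || any(call_rate < 0) || any(call_rate > 1)) {
    stop("call_rate must lie in [0, 1]")
  }
  cohort <- rep_len(as.character(cohort), n)
  if (!all(cohort %in% c("case", "control"))) stop("cohort must be 'case' or 'control'")
  mother_id <- rep_len(as.character(mother_id), n)
  father_id <- rep_len(as.character(father_id), n)
  if (any(!is.na(mother_id) & mother_id == sample_id) ||
      any(!is.na(father_id) & father_id == sample_id)) {
    stop("a sample cannot be its own parent")
  }
  data.frame(sample_id = sample_id, assumed_sex = assumed_sex,
             called_sex = called_sex, call_rate = call_rate, cohort = cohort,
             mother_id = mother_id, father_id = father_id,
             visual_inspection_pass = rep_len(as.logical(visual_inspection_pass), n),
             stringsAsFactors = FALSE)
}

.FEATURE_CLASSES <- c("coding_gene", "promoter", "pop_loss", "pop_gain")

#' Construct a table of annotation features
#'
#' Carrier for the interval tracks consumed by the cascade: coding genes
#' (with strand, needed to derive promoters), explicit promoter windows, and
#' population-variant losses/gains in the style of common-CNV catalogues.
#'
#' @param chrom,start,end interval fields, 1-based inclusive.
#' @param feature_class one of `"coding_gene"`, `"promoter"`, `"pop_loss"`,
#'   `"pop_gain"`.
#' @param name feature label (gene symbol for coding genes).
#' @param strand `"+"`, `"-"` or `"."`.
#' @return a data.frame with one row per feature.
#' @export
annotation_feature <- function(chrom, start, end, feature_class, name,
                               strand = ".") {
  iv <- genomic_interval(chrom, start, end)
  n <- nrow(iv)
  feature_class <- rep_len(as.character(feature_class), n)
  if (!all(feature_class %in% .FEATURE_CLASSES)) {
    stop("feature_class must be one of: ", paste(.FEATURE_CLASSES, collapse = ", "))
  }
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be '+', '-' or '.'")
  data.frame(iv, feature_class = feature_class,
             name = rep_len(as.character(name), n), strand = strand,
             stringsAsFactors = FALSE)
}

#' An empty annotation feature table
#' @return zero-row data.frame with the [annotation_feature()] columns.
#' @export
empty_features <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             feature_class = character(), name = character(),
             strand = character(), stringsAsFactors = FALSE)
}

# Stable per-call identifier used in trace accounting; a function of the
# call's own fields only, so it is invariant under subsetting and reordering.
call_uid <- function(calls) {
  if (nrow(calls) == 0) return(character())
  paste0(calls$sample_id, "|", calls$chrom, ":",
         format(calls$start, scientific = FALSE, trim = TRUE), "-",
         format(calls$end, scientific = FALSE, trim = TRUE), "|", calls$cnv_type)
}
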