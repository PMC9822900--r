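#' Read CNV calls in PennCNV rawcnv dialect
#'
#' One call per line: a region token `chrN:start-end`, `numsnp=`, an optional
#' `length=` (ignored; recomputed from the coordinates), a `state<k>,cn=<c>`
#' token, a sample token (any token without `=`), and optional `startsnp=`,
#' `endsnp=`, `conf=`. Coordinates are taken verbatim as 1-based inclusive.
#' Unrecognized `key=value` tokens are preserved verbatim in the `extra`
#' column and re-emitted by [write_penncnv()].
#'
#' Lines with `cn=2` are rejected: a copy-neutral segment is by definition
#' not a CNV.
#'
#' @param path path to a rawcnv text file.
#' @return a CNV call table (see [cnv_call()]), one row per line, in file
#'   order.
#' @export
read_penncnv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_calls())
  rows <- lapply(seq_along(lines), function(i) {
    parse_penncnv_line(lines[[i]], i)
  })
  do.call(rbind, rows)
}

parse_penncnv_line <- function(line, lineno) {
  tok <- strsplit(trimws(line), "[ \t]+")[[1]]
  fail <- function(...) stop("line ", lineno, ": ", ..., call. = FALSE)
  region <- tok[1]
  m <- regmatches(region, regexec("^(?:[Cc][Hh][Rr])?([0-9XY]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) fail("malformed region token '", region, "'")
  chrom <- m[2]
  if (!chrom %in% .CHROMS) fail(paste0("unknown chromosome '", chrom, "'"))
  rest <- tok[-1]
  kv <- grepl("=", rest, fixed = TRUE)
  state_tok <- grepl("^state[0-9]+,cn=[0-9]+$", rest)
  sample_tok <- rest[!kv & !state_tok]
  if (length(sample_tok) != 1) fail("expected exactly one sample token")
  st <- rest[state_tok]
  if (length(st) != 1) fail("expected exactly one state<k>,cn=<c> token")
  cn <- as.integer(sub("^state[0-9]+,cn=", "", st))
  if (cn == 2L) fail("cn=2 is copy-neutral, not a CNV")
  keys <- sub("=.*$", "", rest[kv & !state_tok])
  vals <- sub("^[^=]*=", "", rest[kv & !state_tok])
  pick <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
  numsnp <- pick("numsnp")
  if (is.na(numsnp)) fail("missing numsnp= token")
  known <- c("numsnp", "length", "startsnp", "endsnp", "conf")
  extra_idx <- !(keys %in% known)
  extra <- if (any(extra_idx)) {
    paste(paste0(keys[extra_idx], "=", vals[extra_idx]), collapse = " ")
  } else ""
  cnv_call(
    sample_id = sample_tok,
    chrom = chrom, start = as.numeric(m[3]), end = as.numeric(m[4]),
    copy_state = cn,
    num_snps = as.integer(gsub(",", "", numsnp)),
    conf = if (is.na(pick("conf"))) NA_real_ else as.numeric(pick("conf")),
    start_snp = pick("startsnp"), end_snp = pick("endsnp"),
    extra = extra
  )
}

# PennCNV HMM state labels for the copy numbers a CNV can take.
.CN_STATE <- c("0" = 1L, "1" = 2L, "3" = 5L, "4" = 6L)

#' Write CNV calls in PennCNV rawcnv dialect
#'
#' The `chr` prefix is re-added on output; `length=` is emitted as
#' `end - start + 1` without digit grouping. Optional fields (`startsnp`,
#' `endsnp`, `conf`) are omitted when `NA`; preserved `extra` tokens are
#' appended.
#'
#' @param calls CNV call table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_penncnv <- function(calls, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- vapply(seq_len(nrow(calls)), function(i) {
    r <- calls[i, ]
    parts <- c(
      sprintf("chr%s:%s-%s", r$chrom, fmt(r$start), fmt(r$end)),
      sprintf("numsnp=%d", r$num_snps),
      sprintf("length=%s", fmt(r$end - r$start + 1)),
      sprintf("state%d,cn=%d", .CN_STATE[[as.character(r$copy_state)]], r$copy_state),
      r$sample_id,
      if (!is.na(r$start_snp)) sprintf("startsnp=%s", r$start_snp),
      if (!is.na(r$end_snp)) sprintf("endsnp=%s", r$end_snp),
      if (!is.na(r$conf)) sprintf("conf=%s", fmt(r$conf)),
      if (nzchar(r$extra)) r$extra
    )
    paste(parts, collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an annotation track from a BED file
#'
#' BED coordinates (0-based, half-open) are converted at the boundary to the
#' internal 1-based inclusive model: `internal_start = bed_start + 1`,
#' `internal_end = bed_end`, so internal length `end - start + 1` equals BED
#' `end - start`. Name and strand columns are used when present.
#'
#' @param path path to a BED3/BED6 file.
#' @param feature_class class assigned to every record (see
#'   [annotation_feature()]).
#' @return an annotation feature table in file order.
#' @export
read_bed_track <- function(path, feature_class) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(
    read.delim(path, header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0) return(empty_features())
  if (ncol(raw) < 3) stop("BED file must have at least 3 columns")
  bed_start <- as.numeric(raw[[2]])
  bed_end <- as.numeric(raw[[3]])
  if (any(bed_end <= bed_start)) {
    stop("BED record with end <= start (empty or negative interval)")
  }
  name <- if (ncol(raw) >= 4) as.character(raw[[4]]) else
    paste0(feature_class, "_", seq_len(nrow(raw)))
  strand <- if (ncol(raw) >= 6) as.character(raw[[6]]) else "."
  strand[!strand %in% c("+", "-")] <- "."
  annotation_feature(chrom = raw[[1]], start = bed_start + 1, end = bed_end,
                     feature_class = feature_class, name = name,
                     strand = strand)
}

#' Parse a printed locus string
#'
#' Accepts the formats found in clinical reports: optional `Chr`/`chr`
#' prefix and dot- or comma-grouped digits, e.g.
#' `"Chr2:72.623.204-72.939.279"`. Used for fixture ingestion only; the
#' package never emits grouped digits.
#'
#' @param x character vector of locus strings.
#' @return interval data.frame (see [genomic_interval()]).
#' @export
parse_locus_string <- function(x) {
  m <- regmatches(x, regexec("^(?:[Cc][Hh][Rr])?([0-9XY]+):([0-9.,]+)-([0-9.,]+)$", x))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) stop("malformed locus string: ", paste(x[bad], collapse = ", "))
  digits <- function(i) as.numeric(gsub("[.,]", "", vapply(m, `[`, character(1), i)))
  genomic_interval(vapply(m, `[`, character(1), 2), digits(3), digits(4))
}

.REPORT_COLS <- c("sample_id", "locus", "chrom", "start", "end", "size_bp",
                  "cnv_type", "genes", "inheritance", "category",
                  "control_frequency_bound")

#' Write a prioritization report as TSV
#'
#' One row per prioritized CNV event (a sib-pair sharing one CNV is one row
#' whose `sample_id` field joins the carriers with commas). Gene lists are
#' comma-joined. Column order is fixed and the file round-trips through
#' [read_report()].
#'
#' @param prioritized prioritized event table (see [prioritize_calls()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(prioritized, path) {
  out <- prioritized
  if (nrow(out) > 0) {
    out$sample_id <- vapply(out$sample_id, paste, character(1), collapse = ",")
    out$genes <- vapply(out$genes, paste, character(1), collapse = ",")
  } else {
    out <- data.frame(matrix(ncol = length(.REPORT_COLS), nrow = 0,
                             dimnames = list(NULL, .REPORT_COLS)))
  }
  out <- out[, .REPORT_COLS]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prioritization report written by [write_report()]
#'
#' @param path report TSV path.
#' @return prioritized event table with `sample_id` and `genes` restored as
#'   list columns.
#' @export
read_report <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = c(genes = "character"))
  if (nrow(df) == 0) {
    df$sample_id <- list()
    df$genes <- list()
    return(df)
  }
  df$sample_id <- I(strsplit(as.character(df$sample_id), ",", fixed = TRUE))
  df$genes <- I(lapply(strsplit(df$genes, ",", fixed = TRUE),
                       function(g) g[nzchar(g)]))
  df
}

#' Read and write sample metadata TSV
#'
#' Columns as produced by [sample_record()].
#'
#' @param path file path.
#' @return sample table ([read_samples()]) or `path` invisibly
#'   ([write_samples()]).
#' @export
read_samples <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  sample_record(df$sample_id, df$assumed_sex, df$called_sex, df$call_rate,
                df$cohort, df$mother_id, df$father_id,
                if ("visual_inspection_pass" %in% names(df))
                  df$visual_inspection_pass else TRUE)
}

#' @rdname read_samples
#' @param samples sample table.
#' @export
write_samples <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write qPCR Ct tables
#'
#' Long CSV with columns `sample_id`, `locus`, `gene` (the literal `"target"`
#' for the assay at the CNV locus, otherwise a housekeeping gene label),
#' `replicate`, `ct` (cycles; `Inf` marks no amplification).
#'
#' @param path file path.
#' @return qPCR measurement table ([read_qpcr()]) or `path` invisibly
#'   ([write_qpcr()]).
#' @export
read_qpcr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "locus", "gene", "replicate", "ct")
  if (!all(needed %in% names(df))) {
    stop("qPCR table must have columns: ", paste(needed, collapse = ", "))
  }
  df$ct <- as.numeric(df$ct)
  df
}

#' @rdname read_qpcr
#' @param plate qPCR measurement table.
#' @export
write_qpcr <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
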