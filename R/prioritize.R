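#' CNV size in base pairs
#'
#' With 1-based inclusive coordinates (the first and last array SNP inside
#' the CNV), the size is `end - start + 1`.
#'
#' @param start,end base positions, 1-based inclusive (vectors recycle).
#' @return numeric vector of sizes in bp.
#' @export
cnv_size <- function(start, end) {
  if (any(start > end)) stop("start must be <= end")
  end - start + 1
}

#' Genes overlapped by each call
#'
#' @param calls CNV call table (or any table with `chrom`, `start`, `end`).
#' @param gene_features annotation table; only `coding_gene` rows are used.
#' @return list (one element per call) of deduplicated, lexicographically
#'   sorted gene names; `character(0)` for calls overlapping no gene.
#' @export
annotate_genes <- function(calls, gene_features) {
  genes <- gene_features[gene_features$feature_class == "coding_gene", , drop = FALSE]
  if (nrow(calls) == 0) return(list())
  if (nrow(genes) == 0) return(rep(list(character(0)), nrow(calls)))
  hits <- GenomicRanges::findOverlaps(as_granges(calls), as_granges(genes),
                                      ignore.strand = TRUE)
  out <- rep(list(character(0)), nrow(calls))
  if (length(hits) > 0) {
    by_call <- split(genes$name[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits))
    for (k in names(by_call)) {
      out[[as.integer(k)]] <- sort(unique(by_call[[k]]))
    }
  }
  out
}

#' Classify trio inheritance of a CNV carried by the child
#'
#' @param mother,father observation of the CNV in each parent: `"present"`,
#'   `"absent"` or `"missing"` (parent not assayed). Vectors recycle.
#' @return character vector: `"de_novo"` (both parents assayed and negative),
#'   `"maternal"` / `"paternal"` (that parent carries it and the other does
#'   not), `"unknown"` (a needed parent is missing and no parent is positive).
#'   Both parents positive is ambiguous and raises an error.
#' @export
infer_inheritance <- function(mother, father) {
  obs <- c("present", "absent", "missing")
  if (!all(mother %in% obs) || !all(father %in% obs)) {
    stop("parental observations must be 'present', 'absent' or 'missing'")
  }
  n <- max(length(mother), length(father))
  mother <- rep_len(mother, n)
  father <- rep_len(father, n)
  if (any(mother == "present" & father == "present")) {
    stop("CNV observed in both parents: inheritance ambiguous (biparental)")
  }
  ifelse(mother == "present", "maternal",
    ifelse(father == "present", "paternal",
      ifelse(mother == "absent" & father == "absent", "de_novo", "unknown")))
}

#' Classify a CNV as microscopic or submicroscopic
#'
#' An event is microscopic -- visible by conventional karyotyping -- if it is
#' terminal (extends to a chromosome end, including unbalanced translocation
#' derivatives) or at least `size_threshold_bp` long; everything else is
#' submicroscopic. Size alone cannot reproduce cytogenetic visibility: a
#' 0.5 Mb terminal duplication is karyotypically visible while an equally
#' sized interstitial event is not, hence the terminal flag is authoritative.
#'
#' @param size_bp event size in bp.
#' @param terminal logical: does the rearrangement reach a chromosome end?
#' @param size_threshold_bp interstitial events at least this long are
#'   microscopic; default 5 Mb.
#' @return character vector `"microscopic"` / `"submicroscopic"`.
#' @export
classify_category <- function(size_bp, terminal, size_threshold_bp = 5e6) {
  ifelse(terminal | size_bp >= size_threshold_bp, "microscopic", "submicroscopic")
}

#' Upper bound on population frequency from control carrier counts
#'
#' Observing `k` carriers among `n` controls caps the plausible population
#' frequency at `(k + 1) / n`: for a CNV absent from all controls the bound
#' is `1/n` (e.g. absence in 4066 controls bounds the frequency below
#' 0.000246).
#'
#' @param n_controls number of QC-passing controls (>= 1).
#' @param n_carriers_in_controls carriers observed among them; default 0.
#' @return numeric frequency bound.
#' @export
control_frequency_bound <- function(n_controls, n_carriers_in_controls = 0) {
  if (any(n_controls < 1)) stop("n_controls must be >= 1")
  (n_carriers_in_controls + 1) / n_controls
}

#' Build the prioritization report from surviving calls
#'
#' Annotates each call with its size, overlapping genes, trio inheritance and
#' microscopic/submicroscopic category, then unifies calls into events: calls
#' from members of the same family (a shared mother or father id in
#' `samples`) with the exact same interval and type count as one event
#' carried by several individuals, mirroring how an affected sib-pair sharing
#' one CNV is reported as a single event. Identical intervals in unrelated
#' individuals remain distinct events (array resolution cannot certify shared
#' breakpoints across families).
#'
#' Optional per-call columns consumed when present: `locus` (label; defaults
#' to `chrom:start-end`), `terminal` (logical, default `FALSE`), `mother_obs`
#' / `father_obs` (`"present"`/`"absent"`/`"missing"`, default `"missing"`).
#'
#' @param calls surviving CNV call table.
#' @param tracks annotation table (for gene content).
#' @param samples sample table (for family links); may be `NULL` (no
#'   unification).
#' @param n_controls control cohort size used for the frequency bound.
#' @param size_threshold_bp passed to [classify_category()].
#' @return event-level data.frame with columns `sample_id` (list column of
#'   carriers), `locus`, `chrom`, `start`, `end`, `size_bp`, `cnv_type`,
#'   `genes` (list column), `inheritance`, `category`,
#'   `control_frequency_bound`.
#' @export
prioritize_calls <- function(calls, tracks, samples = NULL, n_controls,
                             size_threshold_bp = 5e6) {
  if (nrow(calls) == 0) {
    out <- data.frame(locus = character(), chrom = character(),
                      start = numeric(), end = numeric(), size_bp = numeric(),
                      cnv_type = character(), inheritance = character(),
                      category = character(),
                      control_frequency_bound = numeric(),
                      stringsAsFactors = FALSE)
    out$sample_id <- list()
    out$genes <- list()
    return(out[, .REPORT_COLS])
  }
  locus <- if ("locus" %in% names(calls)) calls$locus else
    paste0(calls$chrom, ":", calls$start, "-", calls$end)
  terminal <- if ("terminal" %in% names(calls)) calls$terminal else
    rep(FALSE, nrow(calls))
  mother_obs <- if ("mother_obs" %in% names(calls)) calls$mother_obs else
    rep("missing", nrow(calls))
  father_obs <- if ("father_obs" %in% names(calls)) calls$father_obs else
    rep("missing", nrow(calls))

  size_bp <- cnv_size(calls$start, calls$end)
  genes <- annotate_genes(calls, tracks)
  inheritance <- infer_inheritance(mother_obs, father_obs)
  category <- classify_category(size_bp, terminal, size_threshold_bp)
  freq_bound <- control_frequency_bound(n_controls, 0)

  # Family id per carrier: the parental ids when known, else the sample's own.
  fam <- calls$sample_id
  if (!is.null(samples)) {
    idx <- match(calls$sample_id, samples$sample_id)
    pid <- paste(samples$mother_id[idx], samples$father_id[idx])
    has_parent <- !is.na(idx) &
      (!is.na(samples$mother_id[idx]) | !is.na(samples$father_id[idx]))
    fam[has_parent] <- pid[has_parent]
  }
  event_key <- paste(fam, calls$chrom, calls$start, calls$end, calls$cnv_type)

  first <- !duplicated(event_key)
  out <- data.frame(locus = locus[first], chrom = calls$chrom[first],
                    start = calls$start[first], end = calls$end[first],
                    size_bp = size_bp[first], cnv_type = calls$cnv_type[first],
                    inheritance = inheritance[first],
                    category = category[first],
                    control_frequency_bound = rep_len(freq_bound, sum(first)),
                    stringsAsFactors = FALSE)
  out$sample_id <- I(unname(split(calls$sample_id, factor(event_key, levels = event_key[first]))))
  out$genes <- I(genes[first])
  rownames(out) <- NULL
  out[, .REPORT_COLS]
}

#' Cohort-level summary of the prioritized events
#'
#' Counts are over distinct CNV events (a sib-pair sharing one CNV is one
#' event with two carriers). Deletion/duplication counts follow the
#' convention for microdeletions/microduplications and are taken over the
#' submicroscopic events. The percentage of cases uses the enrolled cohort
#' size as denominator and is rounded to the nearest integer percent.
#'
#' @param prioritized event table from [prioritize_calls()].
#' @param n_enrolled enrolled case count (>= 1).
#' @return one-row data.frame: `n_events`, `n_microscopic`,
#'   `n_submicroscopic`, `n_deletions`, `n_duplications`,
#'   `n_carrier_individuals`, `pct_of_cases`.
#' @export
summarize_events <- function(prioritized, n_enrolled) {
  stopifnot(n_enrolled >= 1)
  sub <- prioritized$category == "submicroscopic"
  carriers <- unique(unlist(prioritized$sample_id))
  data.frame(
    n_events = nrow(prioritized),
    n_microscopic = sum(!sub),
    n_submicroscopic = sum(sub),
    n_deletions = sum(sub & prioritized$cnv_type == "loss"),
    n_duplications = sum(sub & prioritized$cnv_type == "gain"),
    n_carrier_individuals = length(carriers),
    pct_of_cases = round(100 * length(carriers) / n_enrolled)
  )
}
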