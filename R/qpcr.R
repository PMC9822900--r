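#' Normalized Ct (delta Ct) for one sample at one locus
#'
#' `mean(target replicate Cts) - mean(per-gene mean Cts of the three
#' housekeeping references)`. Averaging per gene first, then across genes,
#' keeps the reference stable under unequal replicate counts. A target that
#' never amplified (all replicates `Inf`) yields `+Inf`, the sentinel for
#' zero template copies.
#'
#' @param plate qPCR measurement table (see [read_qpcr()]) -- the rows for
#'   one `sample_id` x `locus`, or a larger table with `sample_id`/`locus`
#'   given.
#' @param sample_id,locus select the assay when `plate` holds several.
#' @param housekeeping expected housekeeping gene labels; all must be present
#'   with at least one finite replicate.
#' @return delta Ct in cycles.
#' @export
delta_ct <- function(plate, sample_id = NULL, locus = NULL,
                     housekeeping = c("CFTR", "BNC1", "RNA")) {
  rows <- plate
  if (!is.null(sample_id)) rows <- rows[rows$sample_id == sample_id, , drop = FALSE]
  if (!is.null(locus)) rows <- rows[rows$locus == locus, , drop = FALSE]
  tgt <- rows$ct[rows$gene == "target"]
  if (length(tgt) == 0) stop("no target replicates for this assay")
  hk <- rows[rows$gene != "target", , drop = FALSE]
  missing_hk <- setdiff(housekeeping, hk$gene)
  if (length(missing_hk) > 0) {
    stop("housekeeping gene(s) entirely missing: ",
         paste(missing_hk, collapse = ", "))
  }
  gene_means <- vapply(housekeeping, function(g) {
    ct <- hk$ct[hk$gene == g]
    ct <- ct[is.finite(ct)]
    if (length(ct) == 0) stop("housekeeping gene ", g, " has no finite replicate")
    mean(ct)
  }, numeric(1))
  if (all(!is.finite(tgt))) return(Inf)
  mean(tgt) - mean(gene_means)
}

#' Comparative-Ct relative quantity
#'
#' `ddct = sample_dct - calibrator_dct`; the relative quantity (target copy
#' dose relative to the diploid calibrator) is `2^(-ddct)`, assuming 100%
#' amplification efficiency per cycle (`efficiency = 2`).
#'
#' @param sample_dct,calibrator_dct normalized Cts in cycles.
#' @param efficiency per-cycle amplification factor; default 2.
#' @return `list(ddct, rq)`.
#' @export
delta_delta_ct <- function(sample_dct, calibrator_dct, efficiency = 2) {
  ddct <- sample_dct - calibrator_dct
  list(ddct = ddct, rq = efficiency^(-ddct))
}

# RQ bin edges between integer copy numbers 0..4 on the diploid-relative
# scale (theoretical RQ = CN/2).
.RQ_EDGES <- c(0.25, 0.75, 1.25, 1.75)

#' Integer copy-number call from a relative quantity
#'
#' Bins centered on the theoretical diploid-relative doses 0, 0.5, 1, 1.5,
#' >=2 copies-of-two: RQ < 0.25 is CN0, `[0.25, 0.75)` CN1, `[0.75, 1.25)`
#' CN2, `[1.25, 1.75)` CN3, >= 1.75 CN4. A value within `guard` of a bin
#' edge is too close to call and returns `NA` (no call).
#'
#' @param rq relative quantity (vectorized), >= 0.
#' @param guard no-call half-width around each bin edge; default 0.05.
#' @return integer vector of copy-number calls; `NA` = no call.
#' @export
call_copy_number <- function(rq, guard = 0.05) {
  if (any(rq < 0, na.rm = TRUE)) stop("relative quantity must be >= 0")
  cn <- findInterval(rq, .RQ_EDGES)
  near_edge <- vapply(rq, function(x) {
    is.finite(x) && any(abs(x - .RQ_EDGES) <= guard)
  }, logical(1))
  cn[near_edge | is.na(rq)] <- NA_integer_
  as.integer(cn)
}

#' Quantify every sample on a plate against its calibrator
#'
#' @param plate qPCR measurement table for one locus.
#' @param calibrator_id sample id of the diploid reference on the plate.
#' @param housekeeping housekeeping gene labels.
#' @param guard no-call band passed to [call_copy_number()].
#' @return data.frame with one row per non-calibrator sample: `sample_id`,
#'   `locus`, `delta_ct`, `delta_delta_ct`, `relative_quantity`, `cn_call`.
#' @export
quantify_plate <- function(plate, calibrator_id = "calibrator",
                           housekeeping = c("CFTR", "BNC1", "RNA"),
                           guard = 0.05) {
  loci <- unique(plate$locus)
  if (length(loci) != 1) stop("quantify_plate expects a single-locus plate")
  ids <- setdiff(unique(plate$sample_id), calibrator_id)
  if (!calibrator_id %in% plate$sample_id) {
    stop("calibrator sample '", calibrator_id, "' not on the plate")
  }
  cal_dct <- delta_ct(plate, calibrator_id, loci, housekeeping)
  rows <- lapply(ids, function(id) {
    dct <- delta_ct(plate, id, loci, housekeeping)
    dd <- delta_delta_ct(dct, cal_dct)
    data.frame(sample_id = id, locus = loci, delta_ct = dct,
               delta_delta_ct = dd$ddct, relative_quantity = dd$rq,
               cn_call = call_copy_number(dd$rq, guard),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Confirm an array-predicted CNV and classify its inheritance in a trio
#'
#' The prediction is confirmed iff the child's integer copy number deviates
#' from 2 in the predicted direction (loss: CN < 2, gain: CN > 2). Parental
#' copy numbers are mapped to trio observations -- a parent deviating in the
#' same direction carries the CNV (`"present"`), a called parent at CN 2 (or
#' deviating the other way) does not (`"absent"`), an unassayed or uncalled
#' parent is `"missing"` -- and inheritance is classified with
#' [infer_inheritance()].
#'
#' @param estimates quantification table from [quantify_plate()].
#' @param cnv_type predicted type, `"loss"` or `"gain"`.
#' @param child_id child sample id (must be in `estimates`).
#' @param mother_id,father_id parent sample ids; `NA` if not assayed.
#' @return `list(confirmed, reason, child_cn, inheritance)`; `inheritance` is
#'   `NA` when the prediction is unconfirmed.
#' @export
confirm_cnv <- function(estimates, cnv_type, child_id, mother_id = NA,
                        father_id = NA) {
  stopifnot(cnv_type %in% c("loss", "gain"))
  deviates <- function(cn) {
    if (is.na(cn)) return(NA)
    if (cnv_type == "loss") cn < 2L else cn > 2L
  }
  cn_of <- function(id) {
    if (is.na(id) || !id %in% estimates$sample_id) return(NA_integer_)
    estimates$cn_call[match(id, estimates$sample_id)]
  }
  child_cn <- cn_of(child_id)
  if (!child_id %in% estimates$sample_id) {
    stop("child '", child_id, "' not among the estimates")
  }
  if (is.na(child_cn)) {
    return(list(confirmed = FALSE, reason = "child_no_call",
                child_cn = NA_integer_, inheritance = NA_character_))
  }
  if (!deviates(child_cn)) {
    return(list(confirmed = FALSE, reason = "no_deviation",
                child_cn = child_cn, inheritance = NA_character_))
  }
  obs <- function(id) {
    cn <- cn_of(id)
    if (is.na(cn)) "missing" else if (isTRUE(deviates(cn))) "present" else "absent"
  }
  list(confirmed = TRUE, reason = "confirmed", child_cn = child_cn,
       inheritance = infer_inheritance(obs(mother_id), obs(father_id)))
}
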