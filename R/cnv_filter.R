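#' CNV filter step IV: call confidence
#'
#' Excludes calls whose confidence (maximum log Bayes factor) is strictly
#' below `min_conf`; a call at exactly the threshold is retained. Calls with
#' no confidence value are excluded: without a score the threshold cannot be
#' certified.
#'
#' @param calls CNV call table.
#' @param min_conf minimum log Bayes factor; default 30.
#' @param cohort trace label.
#' @return `list(calls = retained table, trace = one trace row)`.
#' @export
confidence_filter <- function(calls, min_conf = 30, cohort = "all") {
  uid <- call_uid(calls)
  drop <- is.na(calls$conf) | calls$conf < min_conf
  list(
    calls = calls[!drop, , drop = FALSE],
    trace = trace_entry("IV", cohort, "cnvs", nrow(calls), uid[drop])
  )
}

#' CNV filter step V: consecutive SNP support
#'
#' Excludes calls supported by fewer than `min_snps` consecutive called SNPs;
#' a call at exactly the threshold is retained.
#'
#' @param calls CNV call table.
#' @param min_snps minimum SNP count; default 3.
#' @param cohort trace label.
#' @return `list(calls, trace)`.
#' @export
snp_count_filter <- function(calls, min_snps = 3, cohort = "all") {
  uid <- call_uid(calls)
  drop <- calls$num_snps < min_snps
  list(
    calls = calls[!drop, , drop = FALSE],
    trace = trace_entry("V", cohort, "cnvs", nrow(calls), uid[drop])
  )
}

#' Filter step VI: case/control overlap exclusion
#'
#' A case call overlapped by one or more control calls is discarded. The
#' default follows the strictest reading: any overlap (a single shared base)
#' by a control call of any type excludes. Two optional relaxations support
#' sensitivity analysis: `type_matched` restricts the comparison to control
#' calls of the same type (loss vs gain), and `min_reciprocal` requires a
#' reciprocal overlap fraction.
#'
#' @param case_calls case CNV call table.
#' @param control_calls control CNV call table (should already have passed
#'   the quality gates).
#' @param type_matched only same-type control calls exclude; default `FALSE`.
#' @param min_reciprocal reciprocal overlap fraction in `[0, 1]`; 0 = any
#'   overlap.
#' @return `list(calls, trace)`.
#' @export
control_overlap_filter <- function(case_calls, control_calls,
                                   type_matched = FALSE, min_reciprocal = 0) {
  uid <- call_uid(case_calls)
  if (nrow(case_calls) == 0) {
    drop <- logical(0)
  } else if (type_matched) {
    drop <- rep(FALSE, nrow(case_calls))
    for (tp in c("loss", "gain")) {
      qi <- case_calls$cnv_type == tp
      drop[qi] <- overlaps_any(case_calls[qi, , drop = FALSE],
                               control_calls[control_calls$cnv_type == tp, , drop = FALSE],
                               min_reciprocal)
    }
  } else {
    drop <- overlaps_any(case_calls, control_calls, min_reciprocal)
  }
  list(
    calls = case_calls[!drop, , drop = FALSE],
    trace = trace_entry("VI", "cases", "cnvs", nrow(case_calls), uid[drop])
  )
}

#' Filter step VII: type-matched population-variant exclusion
#'
#' Losses overlapping at least one catalogued population loss are discarded,
#' gains overlapping at least one catalogued population gain likewise;
#' cross-type overlap never excludes.
#'
#' @param calls CNV call table.
#' @param pop_features annotation table restricted to (or containing)
#'   `pop_loss` / `pop_gain` features; other classes are ignored.
#' @return `list(calls, trace)`.
#' @export
population_variant_filter <- function(calls, pop_features) {
  uid <- call_uid(calls)
  drop <- rep(FALSE, nrow(calls))
  for (tp in c("loss", "gain")) {
    cls <- if (tp == "loss") "pop_loss" else "pop_gain"
    qi <- calls$cnv_type == tp
    if (any(qi)) {
      drop[qi] <- overlaps_any(
        calls[qi, , drop = FALSE],
        pop_features[pop_features$feature_class == cls, , drop = FALSE]
      )
    }
  }
  list(
    calls = calls[!drop, , drop = FALSE],
    trace = trace_entry("VII", "cases", "cnvs", nrow(calls), uid[drop])
  )
}

#' Derive promoter windows from stranded gene features
#'
#' The promoter of a gene is the window of `upstream_bp` bases immediately
#' upstream of its transcription start: for a `+` strand gene
#' `[gene_start - upstream_bp, gene_start - 1]`, for a `-` strand gene
#' `[gene_end + 1, gene_end + upstream_bp]`. Windows are clipped at position
#' 1; a window clipped to nothing (gene starting at base 1) is dropped.
#'
#' @param gene_features annotation table of `coding_gene` features; every row
#'   must have strand `+` or `-`.
#' @param upstream_bp promoter window size in bases; default 2000.
#' @return annotation table of `promoter` features named after their genes.
#' @export
derive_promoters <- function(gene_features, upstream_bp = 2000) {
  genes <- gene_features[gene_features$feature_class == "coding_gene", , drop = FALSE]
  if (nrow(genes) == 0) return(empty_features())
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("promoter derivation requires strand '+' or '-' on every coding_gene")
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(1, genes$start - upstream_bp), genes$end + 1)
  end <- ifelse(plus, genes$start - 1, genes$end + upstream_bp)
  keep <- start <= end  # a '+' gene starting at base 1 has no upstream window
  annotation_feature(genes$chrom[keep], start[keep], end[keep],
                     "promoter", genes$name[keep], genes$strand[keep])
}

#' Filter step VIII: gene/promoter residency
#'
#' Retains a call iff it overlaps at least one coding gene body or promoter.
#' Explicit `promoter` features in the track are honored; when none are
#' present, promoters are derived strand-aware from the coding genes (see
#' [derive_promoters()]).
#'
#' @param calls CNV call table.
#' @param features annotation table with `coding_gene` (and optionally
#'   `promoter`) features.
#' @param promoter_upstream_bp window used when promoters must be derived;
#'   default 2000.
#' @return `list(calls, trace)`.
#' @export
genic_filter <- function(calls, features, promoter_upstream_bp = 2000) {
  uid <- call_uid(calls)
  genes <- features[features$feature_class == "coding_gene", , drop = FALSE]
  promoters <- features[features$feature_class == "promoter", , drop = FALSE]
  if (nrow(promoters) == 0) {
    promoters <- derive_promoters(genes, promoter_upstream_bp)
  }
  keep <- overlaps_any(calls, rbind(genes, promoters))
  list(
    calls = calls[keep, , drop = FALSE],
    trace = trace_entry("VIII", "cases", "cnvs", nrow(calls), uid[!keep])
  )
}

#' Cascade configuration
#'
#' Bundles every threshold of the cascade with the study defaults: call rate
#' 0.98, CNV-count trim at mean + 2 SD, minimum log Bayes factor 30, minimum
#' 3 consecutive SNPs, 2 kb promoter window, any-type any-overlap
#' case/control comparison.
#'
#' @param call_rate_threshold step II threshold.
#' @param sd_multiplier step III multiplier.
#' @param min_conf step IV threshold.
#' @param min_snps step V threshold.
#' @param control_type_matched,control_min_reciprocal step VI variants.
#' @param promoter_upstream_bp step VIII promoter window (bp).
#' @param exclude_unknown_sex step I policy for unknown sex fields.
#' @return named list of settings.
#' @export
cascade_config <- function(call_rate_threshold = 0.98, sd_multiplier = 2,
                           min_conf = 30, min_snps = 3,
                           control_type_matched = FALSE,
                           control_min_reciprocal = 0,
                           promoter_upstream_bp = 2000,
                           exclude_unknown_sex = FALSE) {
  list(call_rate_threshold = call_rate_threshold,
       sd_multiplier = sd_multiplier, min_conf = min_conf,
       min_snps = min_snps, control_type_matched = control_type_matched,
       control_min_reciprocal = control_min_reciprocal,
       promoter_upstream_bp = promoter_upstream_bp,
       exclude_unknown_sex = exclude_unknown_sex)
}

#' Run the full prioritization cascade
#'
#' Applies, in order: sample QC steps I-II to both cohorts, step III (CNV
#' count outliers) separately within cases and within controls, call quality
#' gates IV-V to both cohorts' calls, then -- to case calls only -- the
#' case/control overlap exclusion (VI), the type-matched population-variant
#' filter (VII), the gene/promoter residency filter (VIII), and finally a
#' pass-through of the externally supplied visual-inspection flag (IX; a
#' manual review step that the cascade accounts for but cannot compute; calls
#' default to pass when the table has no `visual_inspection_pass` column).
#' Calls belonging to QC-excluded samples are dropped before the call-level
#' gates.
#'
#' @param samples sample table covering both cohorts.
#' @param case_calls,control_calls CNV call tables.
#' @param tracks annotation table carrying `pop_loss`/`pop_gain` and
#'   `coding_gene` (optionally `promoter`) features.
#' @param config settings from [cascade_config()].
#' @return `list(calls = surviving case calls, trace = full trace table,
#'   samples = QC-passing samples)`.
#' @export
run_cascade <- function(samples, case_calls, control_calls, tracks,
                        config = cascade_config()) {
  s1 <- sex_mismatch_filter(samples, config$exclude_unknown_sex)
  s2 <- call_rate_filter(s1$samples, config$call_rate_threshold)
  trace <- rbind(s1$trace, s2$trace)

  qc <- s2$samples
  kept <- list()
  for (co in c("case", "control")) {
    grp <- qc[qc$cohort == co, , drop = FALSE]
    calls <- if (co == "case") case_calls else control_calls
    if (nrow(grp) >= 2) {
      s3 <- cnv_count_outlier_filter(grp, calls[calls$sample_id %in% grp$sample_id, , drop = FALSE],
                                     config$sd_multiplier,
                                     cohort = paste0(co, "s"))
      trace <- rbind(trace, s3$trace)
      grp <- s3$samples
    } else if (nrow(grp) > 0) {
      trace <- rbind(trace, trace_entry("III", paste0(co, "s"), "samples",
                                        nrow(grp), character()))
    }
    kept[[co]] <- grp
  }
  qc <- rbind(kept$case, kept$control)

  filter_cohort <- function(calls, cohort) {
    calls <- calls[calls$sample_id %in% qc$sample_id, , drop = FALSE]
    f4 <- confidence_filter(calls, config$min_conf, cohort)
    f5 <- snp_count_filter(f4$calls, config$min_snps, cohort)
    list(calls = f5$calls, trace = rbind(f4$trace, f5$trace))
  }
  ca <- filter_cohort(case_calls, "cases")
  co <- filter_cohort(control_calls, "controls")
  trace <- rbind(trace, ca$trace, co$trace)

  f6 <- control_overlap_filter(ca$calls, co$calls,
                               config$control_type_matched,
                               config$control_min_reciprocal)
  f7 <- population_variant_filter(f6$calls, tracks)
  f8 <- genic_filter(f7$calls, tracks, config$promoter_upstream_bp)
  trace <- rbind(trace, f6$trace, f7$trace, f8$trace)

  surv <- f8$calls
  vi_pass <- if ("visual_inspection_pass" %in% names(surv)) {
    !isFALSE_vec(surv$visual_inspection_pass)
  } else rep(TRUE, nrow(surv))
  trace <- rbind(trace, trace_entry("IX", "cases", "cnvs", nrow(surv),
                                    call_uid(surv)[!vi_pass]))
  surv <- surv[vi_pass, , drop = FALSE]

  validate_trace(trace)
  list(calls = surv, trace = trace, samples = qc)
}

# NA counts as pass: the flag is externally supplied and optional.
isFALSE_vec <- function(x) !is.na(x) & !x
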