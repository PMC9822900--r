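# hg19 chromosome lengths (chr1..22); the generator never places features on
# the sex chromosomes, sidestepping sex-specific copy number.
.HG19_LEN <- c(
  249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
  159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
  115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
  59128983, 63025520, 48129895, 51304566
)

# The synthetic genome is laid out in 2 Mb slots per chromosome starting at
# 5 Mb. Within a slot: a 50 kb gene at offset 0, a spike niche inside the
# gene at +10..+30 kb, an intergenic spike niche at +400..+420 kb, an 80 kb
# common-pool locus at +1.0 Mb, and a background zone at +1.2..+1.85 Mb where
# random calls and random population features are drawn. The zones never
# touch, so every generated call has a known fate at every cascade step.
.SLOT <- 2e6
.SLOT0 <- 5e6
.GENE_W <- 5e4
.POOL_OFF <- 1e6
.POOL_W <- 8e4
.SPIKE_GENIC_OFF <- 1e4
.SPIKE_FREE_OFF <- 4e5
.SPIKE_W <- 2e4
.BG_OFF <- c(1.2e6, 1.85e6)

slot_coords <- function(i) {
  chrom <- ((i - 1L) %% 22L) + 1L
  slot <- (i - 1L) %/% 22L
  base <- .SLOT0 + slot * .SLOT
  if (any(base + .SLOT > .HG19_LEN[chrom])) {
    stop("layout capacity exceeded: at most ", 22 * 21, " slots")
  }
  list(chrom = as.character(chrom), base = base)
}

gene_layout <- function(n_genes) {
  if (n_genes == 0) return(empty_features())
  sc <- slot_coords(seq_len(n_genes))
  annotation_feature(sc$chrom, sc$base, sc$base + .GENE_W - 1, "coding_gene",
                     sprintf("G%04d", seq_len(n_genes)),
                     ifelse(seq_len(n_genes) %% 2 == 1, "+", "-"))
}

pool_layout <- function(pool_size) {
  if (pool_size == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      cnv_type = character(), stringsAsFactors = FALSE))
  }
  sc <- slot_coords(seq_len(pool_size))
  data.frame(chrom = sc$chrom, start = sc$base + .POOL_OFF,
             end = sc$base + .POOL_OFF + .POOL_W - 1,
             cnv_type = ifelse(seq_len(pool_size) %% 2 == 1, "loss", "gain"),
             stringsAsFactors = FALSE)
}

# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the cohort-level structure of a large SNP-array ARM
#' study: ~16 CNV calls per individual (6316 calls over 396 QC-passing
#' cases), a sex-mismatch rate of ~0.5% (2/450), a call-rate distribution
#' with ~9% of samples below the 0.98 threshold (40/450), and ~3% of
#' remaining samples with grossly inflated CNV counts (12/408).
#'
#' @param n_cases,n_controls cohort sizes.
#' @param seed integer seed; a fixed seed makes every generator output
#'   byte-identical.
#' @param call_rate_mean,call_rate_sd normal call-rate model, truncated to
#'   `[0, 1]`.
#' @param sex_mismatch_rate fraction of samples whose called sex is flipped.
#' @param cnv_count_mean,cnv_count_dispersion negative-binomial CNV count per
#'   sample (mean / size).
#' @param outlier_sample_rate,outlier_multiplier fraction of samples whose
#'   CNV count is multiplied (failed-array analogue).
#' @param common_cnv_pool_size number of common CNV loci shared between the
#'   cohorts; each is guaranteed at least one control carrier.
#' @param sharing_rate per-call probability that a call is drawn from the
#'   common pool rather than the random background.
#' @param n_genes number of coding genes in the deterministic gene track.
#' @param n_background_pop number of random population-variant features
#'   placed in the background zone (in addition to the pool-covering ones).
#' @param spike_specs optional spike table from [spike_specs()].
#' @return validated config list.
#' @export
cohort_config <- function(n_cases = 100, n_controls = 200, seed = 1,
                          call_rate_mean = 0.99, call_rate_sd = 0.008,
                          sex_mismatch_rate = 0.005,
                          cnv_count_mean = 16, cnv_count_dispersion = 8,
                          outlier_sample_rate = 0.03, outlier_multiplier = 4,
                          common_cnv_pool_size = 30, sharing_rate = 0.15,
                          n_genes = 300, n_background_pop = 50,
                          spike_specs = NULL) {
  rates <- c(sex_mismatch_rate, outlier_sample_rate, sharing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (n_cases < 0 || n_controls < 0 || common_cnv_pool_size < 0 || n_genes < 0) {
    stop("counts must be >= 0")
  }
  if (!is.null(spike_specs) && nrow(spike_specs) > 0) {
    pool <- pool_layout(common_cnv_pool_size)
    collide <- overlaps_any(spike_specs, pool)
    if (any(collide & !spike_specs$in_controls)) {
      stop("spike interval collides with a common-pool locus but in_controls=FALSE; ",
           "this would corrupt the spike ground truth")
    }
  }
  list(n_cases = n_cases, n_controls = n_controls, seed = seed,
       call_rate_mean = call_rate_mean, call_rate_sd = call_rate_sd,
       sex_mismatch_rate = sex_mismatch_rate, cnv_count_mean = cnv_count_mean,
       cnv_count_dispersion = cnv_count_dispersion,
       outlier_sample_rate = outlier_sample_rate,
       outlier_multiplier = outlier_multiplier,
       common_cnv_pool_size = common_cnv_pool_size,
       sharing_rate = sharing_rate, n_genes = n_genes,
       n_background_pop = n_background_pop, spike_specs = spike_specs)
}

#' Build spike-in specifications on the synthetic genome
#'
#' Spike `i` is placed in the layout niche of gene `i`: inside the gene body
#' when `genic`, in the intergenic niche of the same slot otherwise, so the
#' placement never touches the common pool, the background zone or another
#' spike. Attributes default to values that pass every call-level gate.
#'
#' @param n number of spikes.
#' @param cnv_type `"loss"` or `"gain"` (recycled).
#' @param genic inside a coding gene? (recycled)
#' @param in_controls also planted in a control sample? (recycled)
#' @param in_pop_track covered by a same-type population feature? (recycled)
#' @param inheritance_truth simulated truth label (recycled).
#' @param num_snps,conf call attributes (recycled).
#' @return spike table consumable by [cohort_config()].
#' @export
spike_specs <- function(n, cnv_type = "loss", genic = TRUE,
                        in_controls = FALSE, in_pop_track = FALSE,
                        inheritance_truth = "de_novo", num_snps = 25,
                        conf = 60) {
  if (n == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      cnv_type = character(), genic = logical(),
                      in_controls = logical(), in_pop_track = logical(),
                      inheritance_truth = character(), num_snps = integer(),
                      conf = numeric(), stringsAsFactors = FALSE))
  }
  genic <- rep_len(genic, n)
  sc <- slot_coords(seq_len(n))
  off <- ifelse(genic, .SPIKE_GENIC_OFF, .SPIKE_FREE_OFF)
  data.frame(chrom = sc$chrom, start = sc$base + off,
             end = sc$base + off + .SPIKE_W - 1,
             cnv_type = rep_len(cnv_type, n), genic = genic,
             in_controls = rep_len(in_controls, n),
             in_pop_track = rep_len(in_pop_track, n),
             inheritance_truth = rep_len(inheritance_truth, n),
             num_snps = rep_len(as.integer(num_snps), n),
             conf = rep_len(as.numeric(conf), n), stringsAsFactors = FALSE)
}

#' Generate the annotation tracks matching a cohort configuration
#'
#' Non-overlapping stranded coding genes on the deterministic layout, a
#' same-type population feature covering every common-pool locus, a same-type
#' population feature over every spike with `in_pop_track = TRUE`, and random
#' background population features confined to the background zone (seeded
#' from the config).
#'
#' @param config from [cohort_config()].
#' @return annotation feature table.
#' @export
generate_tracks <- function(config) {
  genes <- gene_layout(config$n_genes)
  pool <- pool_layout(config$common_cnv_pool_size)
  tracks <- genes
  if (nrow(pool) > 0) {
    tracks <- rbind(tracks, annotation_feature(
      pool$chrom, pmax(1, pool$start - 1e4), pool$end + 1e4,
      ifelse(pool$cnv_type == "loss", "pop_loss", "pop_gain"),
      sprintf("pop_pool_%03d", seq_len(nrow(pool)))))
  }
  sp <- config$spike_specs
  if (!is.null(sp) && any(sp$in_pop_track)) {
    s <- sp[sp$in_pop_track, , drop = FALSE]
    tracks <- rbind(tracks, annotation_feature(
      s$chrom, pmax(1, s$start - 1e3), s$end + 1e3,
      ifelse(s$cnv_type == "loss", "pop_loss", "pop_gain"),
      sprintf("pop_spike_%03d", seq_len(nrow(s)))))
  }
  if (config$n_background_pop > 0) {
    bg <- with_seed(config$seed + 1L, {
      i <- sample.int(22 * 20, config$n_background_pop, replace = TRUE)
      sc <- slot_coords(i)
      w <- round(runif(config$n_background_pop, 2e4, 2e5))
      start <- sc$base + .BG_OFF[1] +
        floor(runif(config$n_background_pop) * (.BG_OFF[2] - .BG_OFF[1] - w))
      annotation_feature(sc$chrom, start, start + w - 1,
                         sample(c("pop_loss", "pop_gain"),
                                config$n_background_pop, replace = TRUE),
                         sprintf("pop_bg_%03d", seq_len(config$n_background_pop)))
    })
    tracks <- rbind(tracks, bg)
  }
  rownames(tracks) <- NULL
  tracks
}

# One random background call in the background zone of a random slot.
random_background_calls <- function(n) {
  if (n == 0) return(NULL)
  i <- sample.int(22 * 20, n, replace = TRUE)
  sc <- slot_coords(i)
  w <- round(runif(n, 5e3, 1.5e5))
  start <- sc$base + .BG_OFF[1] + floor(runif(n) * (.BG_OFF[2] - .BG_OFF[1] - w))
  data.frame(chrom = sc$chrom, start = start, end = start + w - 1,
             copy_state = sample(c(0L, 1L, 3L, 4L), n, replace = TRUE,
                                 prob = c(0.05, 0.5, 0.33, 0.12)),
             num_snps = pmax(1L, stats::rpois(n, w / 8e3)),
             conf = round(pmax(0.1, rnorm(n, 60, 25)), 1),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic case-control cohort with spike-in ground truth
#'
#' Per-sample call rates and sexes are drawn as configured; CNV counts follow
#' a negative binomial with a configurable contamination of count-inflated
#' outlier samples; each call is, with probability `sharing_rate`, a copy of
#' a common-pool locus (every pool locus additionally gets at least one
#' control carrier, so pool calls in cases are always discardable at the
#' case/control comparison) and otherwise a random background call. Spikes
#' are planted in case samples (round-robin); spike carriers are generated
#' clean -- concordant sex, passing call rate, background count capped at the
#' configured mean -- so that a spike's survival depends only on the
#' call-level gates it was constructed to pass or fail.
#'
#' @param config from [cohort_config()].
#' @return `list(samples, case_calls, control_calls, truth)`; `truth` is the
#'   spike table augmented with the carrier `sample_id` (and
#'   `control_sample_id` for spikes planted in controls).
#' @export
generate_cohort <- function(config) {
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_cases + config$n_controls
  empty_truth <- cbind(spike_specs(0),
                       data.frame(sample_id = character(),
                                  control_sample_id = character(),
                                  stringsAsFactors = FALSE))
  if (n == 0) {
    return(list(samples = sample_record(character(0)), case_calls = empty_calls(),
                control_calls = empty_calls(), truth = empty_truth))
  }
  ids <- c(sprintf("case_%04d", seq_len(config$n_cases)),
           sprintf("ctrl_%04d", seq_len(config$n_controls)))
  cohort <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  assumed <- sample(c("male", "female"), n, replace = TRUE)
  called <- assumed
  flip <- runif(n) < config$sex_mismatch_rate
  called[flip] <- ifelse(assumed[flip] == "male", "female", "male")
  call_rate <- pmin(1, pmax(0, rnorm(n, config$call_rate_mean, config$call_rate_sd)))
  counts <- rnbinom(n, mu = config$cnv_count_mean,
                    size = config$cnv_count_dispersion)
  outlier <- runif(n) < config$outlier_sample_rate
  counts[outlier] <- counts[outlier] * config$outlier_multiplier

  sp <- config$spike_specs
  truth <- empty_truth
  if (!is.null(sp) && nrow(sp) > 0) {
    if (config$n_cases == 0) stop("spikes require at least one case sample")
    carrier_idx <- ((seq_len(nrow(sp)) - 1L) %% config$n_cases) + 1L
    truth <- cbind(sp, data.frame(sample_id = ids[carrier_idx],
                                  control_sample_id = NA_character_,
                                  stringsAsFactors = FALSE))
    if (any(sp$in_controls)) {
      if (config$n_controls == 0) stop("in_controls spikes require controls")
      ctl_idx <- config$n_cases +
        ((which(sp$in_controls) - 1L) %% config$n_controls) + 1L
      truth$control_sample_id[sp$in_controls] <- ids[ctl_idx]
    }
    clean <- unique(c(carrier_idx, config$n_cases +
                        ((which(sp$in_controls) - 1L) %% max(1L, config$n_controls)) + 1L))
    clean <- clean[clean <= n]
    called[clean] <- assumed[clean]
    call_rate[clean] <- pmax(call_rate[clean], 0.985)
    counts[clean] <- pmin(counts[clean], config$cnv_count_mean)
  }

  samples <- sample_record(ids, assumed, called, call_rate, cohort)

  pool <- pool_layout(config$common_cnv_pool_size)
  build_calls <- function(idx) {
    out <- list()
    for (i in idx) {
      k <- counts[i]
      if (k == 0) next
      from_pool <- if (nrow(pool) > 0) runif(k) < config$sharing_rate else rep(FALSE, k)
      n_pool <- sum(from_pool)
      rows <- NULL
      if (n_pool > 0) {
        j <- sample.int(nrow(pool), n_pool, replace = TRUE)
        rows <- data.frame(chrom = pool$chrom[j], start = pool$start[j],
                           end = pool$end[j],
                           copy_state = ifelse(pool$cnv_type[j] == "loss", 1L, 3L),
                           num_snps = sample(10:50, n_pool, replace = TRUE),
                           conf = round(runif(n_pool, 35, 200), 1),
                           stringsAsFactors = FALSE)
      }
      bg <- random_background_calls(k - n_pool)
      rows <- rbind(rows, bg)
      rows$sample_id <- ids[i]
      out[[length(out) + 1L]] <- rows
    }
    if (length(out) == 0) return(empty_calls())
    df <- do.call(rbind, out)
    cnv_call(df$sample_id, df$chrom, df$start, df$end, df$copy_state,
             df$num_snps, df$conf)
  }
  case_calls <- build_calls(seq_len(config$n_cases))
  control_calls <- build_calls(config$n_cases + seq_len(config$n_controls))

  # Guarantee every pool locus at least one control carrier.
  if (nrow(pool) > 0 && config$n_controls > 0) {
    j <- seq_len(nrow(pool))
    guard_ids <- ids[config$n_cases + ((j - 1L) %% config$n_controls) + 1L]
    control_calls <- rbind(control_calls, cnv_call(
      guard_ids, pool$chrom, pool$start, pool$end,
      ifelse(pool$cnv_type == "loss", 1L, 3L), 25L, 99))
  }

  if (nrow(truth) > 0) {
    case_calls <- rbind(case_calls, cnv_call(
      truth$sample_id, truth$chrom, truth$start, truth$end,
      ifelse(truth$cnv_type == "loss", 1L, 3L), truth$num_snps, truth$conf))
    planted <- truth[!is.na(truth$control_sample_id), , drop = FALSE]
    if (nrow(planted) > 0) {
      control_calls <- rbind(control_calls, cnv_call(
        planted$control_sample_id, planted$chrom, planted$start, planted$end,
        ifelse(planted$cnv_type == "loss", 1L, 3L), planted$num_snps,
        planted$conf))
    }
  }
  rownames(case_calls) <- rownames(control_calls) <- NULL
  list(samples = samples, case_calls = case_calls,
       control_calls = control_calls, truth = truth)
}

# Housekeeping reference baselines (Ct cycles) used by the plate simulator.
.HK_BASE <- c(CFTR = 24, BNC1 = 23.5, RNA = 26)
.TARGET_BASE <- 25

#' Simulate a qPCR plate for one locus
#'
#' Target Ct for a sample with true copy number `cn` is
#' `calibrator_target_Ct - log2(cn / 2) + noise`: one cycle later per halving
#' of template. A true copy number of 0 never amplifies and yields the `Inf`
#' sentinel. Housekeeping Cts are per-gene baselines plus noise. A diploid
#' `"calibrator"` sample is added to the plate if not among `true_cn`.
#'
#' @param locus locus label.
#' @param true_cn named integer vector: true copy number (0-4) per sample.
#' @param noise_sd Gaussian Ct noise SD in cycles; >= 0.
#' @param replicates replicates per assay.
#' @param seed integer seed.
#' @return qPCR measurement table (see [read_qpcr()]).
#' @export
generate_qpcr_plate <- function(locus, true_cn, noise_sd = 0.15,
                                replicates = 3, seed = 1) {
  stopifnot(noise_sd >= 0, replicates >= 1,
            all(true_cn %in% 0:4), !is.null(names(true_cn)))
  if (!"calibrator" %in% names(true_cn)) {
    true_cn <- c(true_cn, calibrator = 2L)
  }
  with_seed(seed, {
    rows <- lapply(names(true_cn), function(id) {
      cn <- true_cn[[id]]
      tgt <- if (cn == 0) rep(Inf, replicates) else
        .TARGET_BASE - log2(cn / 2) + rnorm(replicates, 0, noise_sd)
      hk <- lapply(names(.HK_BASE), function(g) {
        data.frame(sample_id = id, locus = locus, gene = g,
                   replicate = seq_len(replicates),
                   ct = .HK_BASE[[g]] + rnorm(replicates, 0, noise_sd),
                   stringsAsFactors = FALSE)
      })
      rbind(data.frame(sample_id = id, locus = locus, gene = "target",
                       replicate = seq_len(replicates), ct = tgt,
                       stringsAsFactors = FALSE),
            do.call(rbind, hk))
    })
    do.call(rbind, rows)
  })
}
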