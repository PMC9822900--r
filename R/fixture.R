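#' Bundled reference cohort: the 13 confirmed CNV events of a 450-case ARM
#' study
#'
#' Encodes the published end point of a genome-wide CNV screen in 450
#' individuals with anorectal malformations against 4066 QC-passing controls:
#' 14 carrier individuals (12 singletons and one affected sib-pair) with 13
#' distinct CNV events -- four microscopic anomalies (two unbalanced terminal
#' translocations and two terminal de novo duplications) and nine
#' submicroscopic CNVs (seven microdeletions, two microduplications).
#' Breakpoint coordinates (first/last affected SNP, hg19, 1-based inclusive)
#' are as printed in the study's tables; per-event carried columns give the
#' locus label, terminal status and the qPCR-derived parental observations.
#'
#' The gene track carries the published gene symbols; since the study prints
#' symbols but not coordinates, gene intervals are synthetic placements
#' inside (or overlapping) their CNV, adequate for overlap algebra but not
#' for positional lookup. Confidence scores and SNP counts of the calls are
#' likewise synthetic (chosen comfortably above the quality gates; the study
#' does not print per-call values). The two decoy population features
#' overlap no call.
#'
#' @return `list(samples, calls, control_calls, tracks, n_enrolled = 450,
#'   n_controls = 4066)`; `calls` carries the extra columns `locus`,
#'   `terminal`, `mother_obs`, `father_obs` consumed by
#'   [prioritize_calls()].
#' @export
arm_cohort_fixture <- function() {
  ind <- sprintf("Individual_%d", 1:14)
  sex <- c("female", "female", "male", "male", "female", "male", "male",
           "male", "female", "male", "male", "female", "male", "female")
  # Parents are enrolled (and hence linkable) wherever the study classified
  # inheritance; Individuals 6 and 7 are brothers and share parents.
  mother <- c(NA, NA, "M3", "M4", "M5", "M6", "M6", "M8", "M9", "M10", NA,
              "M12", "M13", "M14")
  father <- c(NA, NA, "F3", "F4", "F5", "F6", "F6", "F8", "F9", "F10", NA,
              "F12", "F13", "F14")
  samples <- sample_record(ind, sex, sex, call_rate = 0.995, cohort = "case",
                           mother_id = mother, father_id = father)

  calls <- cnv_call(
    sample_id = ind,
    chrom = c("11", "22", "3", "17", "2", "2", "2", "4", "7", "17", "9",
              "16", "18", "22"),
    start = c(127078525, 18875445, 171615261, 80545076, 72623204, 72882934,
              72882934, 5162593, 126392369, 33786176, 4973080, 50135837,
              76501085, 18875445),
    end = c(134923456, 21461607, 196805528, 81033874, 72939279, 73015587,
            73015587, 5427691, 126439453, 33968102, 5000904, 51522044,
            77373296, 21461607),
    copy_state = c(1, 1, 3, 3, 1, 3, 3, 1, 1, 3, 1, 1, 1, 1),
    num_snps = c(1500, 600, 4800, 120, 80, 40, 40, 70, 15, 45, 10, 350,
                 220, 600),
    conf = 200
  )
  calls$locus <- c("46,XX,der(11)t(11;16)(q24.2;q22.2)",
                   "46,XX,der(22)t(22;9)(q11.21;p)",
                   "46,XY,dup(3)(q26.31-q29)", "46,XY,dup(17)(q25.3-qter)",
                   "del2p13.2", "dup2p13.2", "dup2p13.2", "del4p16.2",
                   "del7q31.33", "dup17q12", "del9p24.1", "del16q12.1",
                   "del18q32", "del22q11.21")
  calls$terminal <- c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 10))
  calls$mother_obs <- c("missing", "missing", "absent", "absent", "present",
                        "present", "present", "absent", "absent", "present",
                        "missing", "absent", "absent", "absent")
  calls$father_obs <- c("missing", "missing", "absent", "absent", "absent",
                        "absent", "absent", "present", "present", "absent",
                        "missing", "absent", "absent", "absent")

  g <- function(chrom, start, end, name, strand = "+") {
    annotation_feature(chrom, start, end, "coding_gene", name, strand)
  }
  tracks <- rbind(
    g("11", 128556430, 128683162, "FLI1"),
    g("22", 19744226, 19771116, "TBX1"),
    g("3", 187871064, 188608460, "LPP"),
    g("17", 80477593, 80562483, "FOXK2"),
    g("2", 72700000, 73100000, "EXOC6B", "-"),
    g("4", 5053858, 5502242, "STK32B", "-"),
    g("7", 126078651, 126893932, "GRM8", "-"),
    g("9", 4985033, 5128183, "JAK2"),
    g("17", 33790000, 33810000, "AP2B1"),
    g("17", 33815000, 33820000, "LINC02001"),
    g("17", 33825000, 33830000, "LOC107985033"),
    g("17", 33835000, 33845000, "PEX12"),
    g("17", 33850000, 33870000, "SLFN12L"),
    g("17", 33875000, 33895000, "SLFN14"),
    g("17", 33900000, 33901000, "SNORD7"),
    g("16", 50150000, 50200000, "ADCY7"),
    g("16", 50300000, 50350000, "HEATR3"),
    g("16", 50450000, 50500000, "PAPD5"),
    g("16", 50600000, 50650000, "BRD7"),
    g("16", 50750000, 50800000, "CYLD"),
    g("16", 50900000, 50950000, "NKD1"),
    g("16", 51050000, 51100000, "NOD2"),
    g("16", 51200000, 51250000, "SNX20"),
    g("16", 51350000, 51400000, "SALL1"),
    g("18", 76550000, 76650000, "SALL3"),
    g("18", 76800000, 76900000, "ATP9B"),
    g("18", 77050000, 77150000, "NFATC1"),
    annotation_feature("1", 1000000, 1100000, "pop_loss", "decoy_pop_loss"),
    annotation_feature("1", 2000000, 2100000, "pop_gain", "decoy_pop_gain")
  )

  list(samples = samples, calls = calls, control_calls = empty_calls(),
       tracks = tracks, n_enrolled = 450, n_controls = 4066)
}
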