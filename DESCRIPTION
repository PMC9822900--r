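Package: cnvcascade
Title: Case-Control CNV Prioritization Cascade with qPCR Confirmation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filtering cascade for SNP-array copy number variant (CNV) calls
    in a case-control cohort: per-sample quality control (sex concordance,
    call rate, CNV-count outliers), per-call quality gates (confidence score,
    consecutive SNP support), exclusion of calls overlapped by control CNVs,
    type-matched population-variant filtering, and gene/promoter residency,
    with full per-step accounting. Surviving calls are turned into a
    prioritization report (size, gene content, trio inheritance,
    microscopic/submicroscopic category, control-frequency bound) and
    confirmed by comparative-Ct (delta-delta-Ct) qPCR relative quantification
    against three housekeeping references. Includes a synthetic cohort
    generator with spike-in ground truth and a bundled fixture of thirteen
    confirmed CNV events from a 450-case anorectal-malformation cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
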