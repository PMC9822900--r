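---
title: "A case-control CNV prioritization cascade with qPCR confirmation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A case-control CNV prioritization cascade with qPCR confirmation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvcascade)
```

## The problem

SNP-array molecular karyotyping of a rare-disease cohort yields thousands of
copy number variant (CNV) calls per study, the vast majority of which are
technical artifacts or benign population variation. To find the handful of
potentially disease-causing events, studies of this design apply a stringent
cascade: per-sample quality control, per-call quality gates, exclusion of
anything also seen in healthy controls, exclusion of catalogued population
variants, and a requirement that the event touch functional sequence. Each
step must be auditable — reviewers expect a per-step accounting of exactly
how many samples and calls went in, survived, and were dropped.

`cnvcascade` implements that cascade for calls in the PennCNV rawcnv dialect,
turns the survivors into a prioritization report (size, gene content, trio
inheritance, cytogenetic category, control-frequency bound), and models the
standard confirmation experiment: comparative-Ct (ΔΔCt) qPCR against three
housekeeping references, with integer copy-number calling and trio de novo /
maternal / paternal classification.

## Coordinates

All internal coordinates are 1-based and inclusive on both ends — the
convention of printed first/last-SNP breakpoints — so an event's size is
`end − start + 1` and a single-base interval has `start == end`. BED input
(0-based, half-open) is converted at the boundary: `internal_start =
bed_start + 1`, `internal_end = bed_end`, which preserves lengths exactly.
Interval joins run through `GenomicRanges::findOverlaps`, whose closed
1-based semantics match the internal model with no shifting.

## The cascade and its thresholds

| Step | Unit | Rule | Default |
|------|------|------|---------|
| I    | samples | called sex ≠ assumed sex | — |
| II   | samples | call rate strictly below threshold | 0.98 |
| III  | samples | CNV count > mean + k·SD (per cohort) | k = 2 |
| IV   | calls | confidence (max log Bayes factor) strictly below | 30 |
| V    | calls | fewer consecutive called SNPs than | 3 |
| VI   | case calls | overlapped ≥1 bp by any control call | any type |
| VII  | case calls | type-matched overlap with a population variant | — |
| VIII | case calls | overlaps no gene body or promoter | 2 kb window |
| IX   | case calls | externally supplied visual-inspection flag | pass |

Boundary semantics are deliberate and tested: a sample at exactly the call
rate threshold, a call at exactly confidence 30 or exactly 3 SNPs, are all
*retained* (the exclusions are strict inequalities), while a single shared
base suffices to exclude at step VI.

Design choices where the procedure was genuinely open:

* **Step III one-sided, sample SD.** "Exceeding twice the standard deviation
  of the mean count" is read as `count > mean + 2·SD` with the n−1 sample
  SD, applied separately within cases and controls. Excess calls flag a
  failed array; a deficit does not, so a two-sided trim would exclude
  implausibly. The step is not idempotent — removing outliers shifts the
  mean and SD of the survivors — and the suite asserts exactly that rather
  than pretending otherwise.
* **Missing confidence excludes at IV.** Without a score, a threshold on the
  maximum log Bayes factor cannot be certified.
* **Step VI any-type, any-overlap.** The strictest defensible reading;
  `type_matched` and `min_reciprocal` variants are exposed as options for
  sensitivity analysis, and the interval-join implementation is held equal
  to a brute-force all-pairs oracle over randomized instances in the tests.
* **Promoters are 2 kb strand-aware upstream windows** (`[start−2000,
  start−1]` on `+`, `[end+1, end+2000]` on `−`, clipped at base 1), derived
  only when the track carries no explicit promoter features. 2 kb is a
  common convention; the window is a parameter.
* **Step IX is a pass-through flag.** A manual intensity-plot review cannot
  be computed, but the cascade still accounts for it in the trace so that
  the bookkeeping covers all nine steps.
* **Steps VII and VIII commute** (both are independent exclusions); the
  suite asserts this rather than relying on a particular order.

Every step returns a trace row with the conservation identity
`n_in = n_out + n_excluded` and the identifiers of what was dropped;
`validate_trace()` re-checks the identity over the whole cascade.

## The prioritization report

Surviving calls are annotated (size, overlapping genes sorted and
deduplicated, trio inheritance from parental present/absent/missing
observations, microscopic vs submicroscopic category, and the control
frequency bound `(carriers + 1)/n_controls`) and unified into events.

Two categorization choices matter:

* **Microscopic = terminal OR ≥ 5 Mb.** Cytogenetic visibility is not a pure
  size property — a 0.5 Mb terminal duplication is karyotypically visible
  while an equally sized interstitial event is not — so the caller-supplied
  terminal flag is authoritative and the size threshold only catches large
  interstitial events.
* **Event unification is exact-match within a family.** An affected sib-pair
  sharing a CNV (same printed interval, same type, shared parent) counts as
  one event with two carriers. Unification is *not* applied across
  families: array resolution cannot certify that unrelated individuals with
  the same printed breakpoints share a true event, and the bundled
  reference cohort contains exactly this situation (two unrelated carriers
  of a 22q11.21 deletion with identical printed coordinates that are two
  events, alongside a sib-pair that is one).

The percentage-of-cases summary uses the *enrolled* cohort size as
denominator (not the QC-passing count) and rounds to the nearest integer
percent; both choices are parameters of `summarize_events()` in effect,
since the caller supplies the denominator. Deletion/duplication counts in
the summary follow the microdeletion/microduplication convention and are
taken over submicroscopic events.

## ΔΔCt copy-number confirmation

For each sample × locus, `delta_ct()` subtracts the housekeeping reference
from the target Ct, averaging each housekeeping gene's replicates first and
then the three per-gene means — an order that keeps the reference stable
under unequal replicate counts (the suite pins this with hand-computed
arithmetic: housekeeping means 23, 24, 25 give reference 24). `ΔΔCt` against
a diploid calibrator on the same plate yields the relative quantity
`RQ = 2^(−ΔΔCt)` (100% efficiency assumed, configurable), and
`call_copy_number()` bins RQ at 0.25/0.75/1.25/1.75 — the midpoints between
the theoretical doses 0, 0.5, 1, 1.5, ≥2 — with a ±0.05 no-call guard band
around each edge.

The guard bands make the caller abstain rather than guess near a boundary,
so accuracy is reported *among made calls*; abstention is tracked
separately. This matters quantitatively: with Ct noise of 0.15 cycles and 3
replicates, the CN = 3 bin is narrow on the log2 scale and abstains in
roughly a tenth of assays while accuracy among calls stays near 99%.
Inheritance classification is a deterministic function of the called trio
copy numbers, so labels provably match the simulation truth whenever the
three members are called correctly; a miscalled (but called) parent will
mislabel, which is a property of the noise level, not of the mapping.

A true copy number of zero never amplifies; the simulator emits an `Inf` Ct
sentinel and the pipeline calls CN 0 from the resulting `RQ = 0`.

## The synthetic cohort generator

`generate_cohort()` emulates the cohort-level structure such a study
reports, not per-probe array signal. Defaults are fixed from that
structure: ~16 CNV calls per individual, a call-rate distribution
(mean 0.99, SD 0.008, truncated to [0, 1]) putting roughly 9% of samples
below the 0.98 gate, a 0.5% sex-mismatch rate, and 3% of samples with
count-inflated failed arrays. CNV counts are negative-binomial: the
cascade's outlier trim only needs an overdispersed count model, and the
generator makes the contamination explicit instead of hiding it in the
tail.

The synthetic genome is a deterministic slot layout (a 50 kb gene, spike
niches inside and outside the gene, an 80 kb common-CNV locus, and a
background zone per 2 Mb slot on the autosomes): every generated call
therefore has a knowable fate at every step, which is what makes exact
spike-in assertions possible. Spikes constructed to pass every gate are
recovered at exactly 100%; spikes planted in controls or covered by a
type-matched population feature die exactly at steps VI / VII; non-genic
spikes die exactly at VIII. Spike carriers are generated clean (concordant
sex, passing call rate, background count capped at the configured mean) so
a spike's fate depends only on the gates it was built to pass or fail.
Common-pool loci are guaranteed at least one control carrier, so shared
CNVs are always discardable at step VI.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: per-SNP log R ratio / B allele frequency signal,
breakpoint uncertainty, genotyping batch effects, realistic gene density or
population-variant architecture, and sex-chromosome copy number (the layout
is autosomal). Conclusions about caller performance on real arrays require
real arrays.

## The bundled reference cohort

`arm_cohort_fixture()` packages the published end point of a genome-wide CNV
screen in 450 individuals with anorectal malformations vs 4066 QC-passing
controls: 14 carrier individuals, 13 distinct CNV events (four microscopic
anomalies, nine submicroscopic CNVs of which seven are microdeletions), with
breakpoints exactly as printed (hg19). Printed sizes of the six rare
submicroscopic loci equal `end − start + 1` for every row, confirming the
1-based inclusive reading of the coordinates. Gene symbols are as published,
but their interval placements are synthetic (the source prints symbols, not
coordinates), as are per-call confidence scores and SNP counts — adequate
for overlap algebra and for exercising the cascade end-to-end, not for
positional lookup. Running the fixture through the cascade reproduces the
published counts: 13 events, 9 submicroscopic, 7 microdeletions, 14
carriers, 3% of 450 enrolled cases, frequency bound 1/4066 < 0.0003.

## Problem sizes

The test suite and the acceptance script run the cascade on cohorts of tens
of samples with a few thousand calls (100 random 8 × 12 cohorts for the
conservation property; 100 randomized ≤50 × ≤200 instances for the oracle
equality; 40 × 80 with 20 spikes for recovery; 200 simulated trios for qPCR
accuracy), sizes at which the brute-force oracles remain exact and the whole
suite completes in well under a minute per property. The analysis drivers
use a 100 × 200 cohort. Scaling the cascade itself is not a concern: the
joins are interval-tree based and the published study's ~50k calls are far
below `findOverlaps` limits.

## Known limitations

* Sex chromosomes receive no special handling in sex-discordant contexts;
  X/Y calls pass through the same gates as autosomal calls.
* Called sex is consumed from the metadata table, never recomputed from
  genotypes (intensity data are out of scope).
* Step VI has no frequency threshold: one overlapping control call
  excludes, which is stringent and will discard true variants that are rare
  but not absent in controls.
* qPCR efficiency is assumed 100% per cycle; no standard-curve correction.
* The breakpoints of a printed event are first/last-array-SNP positions;
  true breakpoints are unknown, which is why cross-family unification is
  refused.
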