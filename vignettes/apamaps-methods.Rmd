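---
title: "apamaps: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{apamaps: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apamaps)
```

This vignette records the scientific model behind each stage of the
package, the parameters that matter with their defaults and units, the
assumptions of the synthetic-data generator, and the choices made where
the design was genuinely open. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## Coordinate conventions

All in-memory intervals are `GRanges` (1-based, closed), the native
container of the Bioconductor stack; every file read or written (BED6,
bedGraph) is BED-convention 0-based half-open, converted at the I/O
boundary. "Upstream" and "downstream" are always in transcript
orientation: downstream of a position on the minus strand means smaller
genomic coordinates, and fetched sequences are reverse-complemented so
motifs are always written in transcript sense. Motifs may be given in
RNA or DNA alphabet; U is normalized to T internally.

## PAS cluster model

Targeted 3' end sequencing places the read 3' end at the
cleavage-and-polyadenylation site, but cleavage is heterogeneous over a
few nucleotides, so usage is quantified per *cluster* rather than per
base. Coverage tracks store per-position 3' end counts (not full-read
depth); the combined track over all samples defines cluster boundaries
shared by every sample, which makes per-sample usage directly
comparable. Clusters are maximal runs of positions with count strictly
greater than `min_per_position` (default 10 reads); clusters with fewer
than `min_total` (20) combined reads are removed. The cluster PAS is the
argmax position; ties are resolved to the 3'-most position in transcript
orientation, i.e. the largest coordinate on plus and the smallest on
minus — the strand-aware reading of a 3'-most rule.

Whether the per-position rule should use 3' end counts or full-read
depth is genuinely open for this assay type; 3' end counts were chosen
because the 3' end is the measurement of interest and full-read depth
would mix in positions the read merely traverses.

### Internal-priming filters

Oligo-dT priming on genome-templated A stretches produces spurious
3' ends. Two sequence heuristics flag them:

* `fail_consecutive_A`: more than 6 consecutive genomic adenosines
  (transcript sense) directly after the assigned PAS;
* `fail_A_rich_window`: more than 7 adenosines within the 10 nt directly
  downstream of the cluster's 3' boundary.

The two filters anchor differently (PAS versus cluster boundary) on a
literal reading of their definitions. Flags accumulate rather than
short-circuit, so any subset of filters can be reported and the
filtering funnel reconstructed; the clean set is the flag-free,
exon-assigned subset.

### Hexamer and reference filters

Clusters must contain one of the two strongest PAS hexamers (AAUAAA or
AUUAAA, searched as AATAAA/ATTAAA on the sense strand) and must contain
a site from a reference PAS database (slack 0 by default: the site must
fall inside the cluster; a `slack` argument widens the match window).

`filter_hexamer()` takes a `flank_upstream` argument (default 0, the
strict cluster interval). The biological hexamer sits 10–20 nt upstream
of the cleavage site; real 3' end clusters are usually wide enough to
reach it, but narrowly focused clusters — such as those produced by this
package's simulator, whose read jitter is only ±5 nt — are not. The
simulation-facing pipeline therefore extends the search 30 nt upstream
of the cluster (`hexamer_flank = 30` in `run_apa_pipeline()`), which is
where the hexamer must lie for any bona fide site; the strict default
remains for data whose clusters are wide.

### Exon assignment and usage

A cluster joins a terminal exon when its PAS position (not merely its
interval) falls inside a same-strand exon; if two same-strand exons
overlap the PAS, the exon whose annotated 3' end is nearest downstream
wins, since that is the transcription unit most likely to have produced
the cleavage event. Relative usage is the cluster's count over the
exon's total per sample; an exon-sample with zero total yields missing
usage, never zero, so empty samples cannot masquerade as absent
isoforms.

## APA change calling

Replicate knockdown-control pairs are compared by usage delta
(knockdown minus control). A PAS is called changed when at least
`n_support = 2` of the pairs move at least `delta_thresh = 0.10` in the
same direction and *no* pair moves the opposite way by more than
`opposite_tolerance` (default 0: any opposite-sign delta disqualifies —
the literal reading of "no comparison in the opposite direction"; the
tolerance is configurable because the literal rule is noise-sensitive at
low depth). Missing deltas neither support nor disqualify. Confident
non-changing exons require every sample total at least `min_reads = 10`
and every PAS delta within `max_delta = 0.05`.

For dPDUI tables the sign convention is control minus knockdown distal
usage, so positive dPDUI means the knockdown shifts expression toward
the proximal PAS — the regulator lengthens the 3'UTR. Thresholds:
changing |dPDUI| ≥ 0.20 with adjusted p < 0.05; non-changing
|dPDUI| < 0.05 with p > 0.05; everything between is unclassified rather
than silently binned.

Compartment comparison: an exon is *shared* when significant in the
same direction in both compartments, and *compartment-specific* only
when significant in one and confidently non-changing in the other —
absence of evidence in the second compartment is not evidence of
stability.

Overlap statistics between target sets are the two-tailed Fisher exact
test on the 2×2 membership table over the jointly quantified universe,
the Jaccard index, and the same-direction fraction over the
intersection. No multiple-testing correction is applied to single
pairwise comparisons; `p.adjust`-style correction can be layered by the
caller.

## Positional maps

`event_window_matrix()` builds a binary event × offset matrix over
offsets −window..window (default ±300 nt; wide enough to contain the
upstream regulatory region, configurable since no single width is
canonical) around the pPAS or dPAS anchor, strand-aware so minus-strand
events mirror plus-strand geometry exactly. The per-offset binding
fraction carries a band from 100 bootstrap resamples of events (25th
and 75th percentiles of the resampled means; `quantile()` type 7), and
enrichment against a non-changing set is a per-offset two-tailed Fisher
exact test on (bound, unbound) × (regulated, control). Two-sided p uses
the probability-mass convention (sum of hypergeometric outcomes no more
likely than observed) — the convention `fisher.test` implements and the
one verified against exhaustive enumeration in the test suite. Raw p per
position is reported, matching the heatmap-style presentation; signed
−log10 p rows order RBPs by their peak significance, with depletion
negative.

## Motif maps and spacing

Motif matches use IUPAC patterns via `Biostrings::matchPattern(fixed =
FALSE)`, reporting all overlapping occurrences. A match counts toward
the window "at offset x" when its *start* lies in
[x − w/2, x + w/2); even windows bias 1 nt left. Window widths follow
motif length: 10 nt for 4-mers, 20 nt for 6-mers, with a 5-nt running
mean; G/C profiles use a 10-nt running mean, and positions near the
profile edge average over shrunken windows rather than being dropped.
A/U content is the complement of G/C on the ACGT alphabet; ambiguous
bases leave both numerator and denominator.

The UGUA-to-hexamer linker is measured as intervening nucleotides:
hexamer start minus the end of the nearest upstream UGUA, pairing the
hexamer nearest the cleavage site within a ±150 nt search radius. The
measurement endpoints are a package choice — the quantity of interest
is the stretch the CPA machinery must loop or the helicase must unwind,
which is the intervening sequence. Only PAS with a focal-RBP peak
within 100 nt qualify when a peak set is supplied; passing `NULL`
skips the binding filter so unbound reference sets can be profiled.

## DMS accessibility

Dimethyl sulfate modifies accessible (unpaired) adenosines and
cytosines; low mutation rates imply base-pairing. For each motif
occurrence within 100 nt upstream of a PAS, the score is the maximum
mutation rate over the occurrence's adenosines with coverage at least
100 reads; occurrences with no sufficiently covered A are excluded
("sufficient data" operationalized as ≥ 1 covered A) rather than scored
zero, since zero would mimic perfect structure. Both pooled-occurrence
scoring (default) and a per-PAS maximum (`per_pas_max`) are available,
matching the two presentation styles such analyses use. Distributions
are compared with the two-sample two-tailed Kolmogorov–Smirnov test,
exact when the smaller group has at most 10 observations and asymptotic
otherwise (mutation rates are effectively continuous, so ties are rare
and the asymptotic form is adequate at larger n).

## The synthetic experiment

The generator's defaults are the study conditions the package is tested
under: 200 terminal exons of 2,000 nt on alternating strands, 2 PAS per
exon (transcript offsets 900 and 1,900), 25 lengthened + 25 shortened +
150 non-changing genes, usage shift 0.30, Poisson(300) reads per exon
and sample across control/knockdown × whole/nuclear/cytoplasmic × 3
replicates (18 samples), read 3' ends jittered uniformly ±5 nt, 20% of
exons carrying a 10-nt genomic A-run decoy fed by Poisson(10) reads per
sample, regulator CLIP peaks at Normal(−50, 15) nt from the distal PAS
of lengthened genes over a uniform background RBP, UGUA-to-hexamer
linkers of 120 nt (regulated distal PAS) versus 50 nt (all others), and
DMS rates with means 0.01 (structured motifs of lengthened distal PAS)
versus 0.10 (open) at Poisson(200) coverage, Beta-distributed so rates
stay in [0, 1].

Construction guarantees worth knowing when interpreting test results:

* every true PAS has a hexamer ending 10–20 nt upstream of cleavage and
  an A-free 20 nt directly downstream, so compliant sites never trip
  the internal-priming filters by construction;
* background A-runs of 6+ nt are broken and planted elements are
  C-flanked, so the only A-run artifacts are the planted decoys;
* stray UGUA occurrences between the planted UGUA and the cleavage site
  are scrubbed so the planted linker length is the measured one;
* nuclear and cytoplasmic fractions share usage vectors by default
  (PAS choice modeled as nuclear); `cytoplasm_only_shift` plants
  cytoplasm-restricted shifts to exercise the compartment comparison.

What the generator does *not* emulate: sequencing error, read-level
artifacts, expression-dependent coverage heterogeneity, overlapping
genes, alternative splicing of terminal exons, and correlated noise
between replicates. Passing tests therefore demonstrate correctness of
the implemented rules and recoverability of planted signal under clean
conditions, not robustness to every pathology of real libraries.

Every generator is deterministic given `seed`; the pipeline derives
sub-seeds (seed + fixed offsets) per stage so stages can be rerun
independently with identical results.

## Problem sizes and numerical notes

The shipped tests and acceptance script use 200–400 genes, 200 random
coverage tracks of up to 1,000 nt for oracle equivalence, 100–200
events per RNA-map set, 200 sites per spacing group, and exhaustive
2×2 enumeration up to margins of 30 — sizes chosen so planted-signal
recovery is statistically unambiguous while a full run stays
interactive. Usage rows sum to 1 within 1e-12 wherever defined;
exact-test agreement is checked to 1e-9 relative; bootstrap bands are
seeded and reproducible. Degenerate inputs (empty peak sets, zero-depth
samples, empty event sets) return empty or missing results, never NaN
aggregates.

## Known limitations

* The cluster caller assumes combined coverage fits in memory per
  chromosome-strand; it is not streamed.
* Replicates are paired by index; if an experiment's pairing is
  different, pass an explicit pairing list.
* The hexamer search flank and the "nearest upstream UGUA" linker rule
  are interpretations where no single published definition exists; both
  are parameters or documented conventions rather than hard-coded
  behavior.
* Peak calling itself is out of scope: the package consumes (or
  simulates) peak intervals and never re-implements a CLIP peak model.
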