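---
title: "Single-cell CNA inference and TE-biopsy concordance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell CNA inference and TE-biopsy concordance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicCNA)
```

## The scientific question

Pre-implantation genetic testing for aneuploidy (PGT-A) profiles a few
trophectoderm (TE) cells of a blastocyst by low-pass CNV-seq. A "mosaic"
result — an intermediate copy-number level implying that euploid and
aneuploid cells coexist in the biopsy — leaves the clinic with a hard
question: if such an embryo is transferred and a healthy infant is born,
does the infant carry cells with the embryo's mosaic copy-number
alteration (CNA)? Answering it requires calling chromosome-scale CNAs in
hundreds of individual blood cells per infant and comparing every called
event against the TE biopsy's reported CNAs. This package implements that
pipeline end to end, together with a synthetic-data generator that
reproduces the statistical structure of MALBAC-amplified single-cell
whole-genome data, so the full analysis is testable without
controlled-access human data.

## The single-cell copy-number model

Reads from each cell (already aligned, deduplicated and MAPQ-filtered
upstream) are counted into a genome-wide scaffold of variable-size bins
(~1.0 Mb for single cells; ~2.5 Mb for TE CNV-seq). Variable sizing means
equal *expected* reads per bin under a diploid genome; the scaffold also
carries per-bin GC fractions and a bad-bin mask. Masked bins keep their
coordinates but are excluded from every statistic, so segment coordinates
remain genomic.

Counts become copy ratios in three fixed stages:

1. **Depth normalization** — divide by the cell's mean count over unmasked
   autosomal bins. Sex chromosomes never enter a baseline: a male X/Y at
   copy number 1 would otherwise bias the genome mean.
2. **GC correction** — a LOWESS fit of ratio against bin GC (span 0.3,
   3 robustness iterations, fitted values floored at 0.05) captures the
   amplification chemistry's GC dependence; each ratio is divided by the
   fitted value. The curve is estimated on chromosome-median-flattened
   ratios: GC is a bin-scale covariate, so chromosome-scale copy-number
   structure (a whole-chromosome gain, or a male X at half depth) is
   divided out before the fit and the fitted curve is then applied to
   the raw ratios. Without the flattening, a large event inflates the
   smoother's robustness scale and the curve bends toward the event
   wherever its chromosome dominates a GC stratum, eroding the very
   signal being measured.
3. **Plate-control correction** — cells amplified on one 96-well plate
   share a reproducible amplification wave; the per-bin 10%-trimmed mean
   across the plate's GC-corrected cells (renormalized to mean 1) is
   divided out. The trimming protects the control against aneuploid
   cells. The cell under test is not excluded from its own plate control:
   at ~96 cells its self-contribution is about 1%. On sex chromosomes the
   control's *expected copy ratio* — known from the plate's cell sexes
   (X: 0.5 per male cell, 1 per female; Y: 0.5 per male, 0 per female) —
   is divided out of the control: the pooled X of an all-male plate sits
   at ratio ~0.5 times the amplification wave, and the control must keep
   the wave (so it cancels in correction) while shedding the copy state
   (which belongs to the cells, not the bias).

Each stage renormalizes so the unmasked autosomal mean is exactly 1;
renormalization is idempotent, and the pipeline refuses to apply control
correction to a profile that has not been GC-corrected.

## Segmentation

Each chromosome's ratio series is segmented independently by circular
binary segmentation (CBS) on `log2(ratio + eps)` with `eps = 1e-3` (a
variance-stabilizing transform that tolerates zero-count bins; means are
reported back on the linear scale). The core statistic scans all boundary
pairs `1 <= i < j <= n` of the circularized series — every circular split
appears exactly once, with a boundary at the origin represented by
`j = n` — and maximizes the pooled-variance two-sample t statistic
between the arc and its complement. Ties resolve to the smallest `(i, j)`;
a perfect step yields an infinite statistic; a constant series yields the
zero sentinel.

Significance uses `alpha = 1e-10` with `undo.prune = 0.05`. An alpha that
small is far below what any feasible permutation test can resolve
(10^4 permutations resolve ~10^-4), which forces a hybrid scheme. The
decision rule pinned in `arc_significance()` is:

* the analytic tail bound — the Gaussian union bound
  `p = min(1, n(n-1) * pnorm(-T))` over the `n(n-1)/2` arcs — grants
  significance when it falls at or below `alpha / 10`;
* when the bound exceeds `alpha`, the split is non-significant outright
  (the analytic stage is the only route to significance, so permutations
  could not change the decision);
* only in the narrow band between `alpha / 10` and `alpha` are
  permutations drawn (early-stopped as soon as enough exceedances
  guarantee non-significance at the full permutation budget).

The union bound is conservative relative to sharper scan-statistic
approximations; the cost is a modest loss of power near the detection
boundary, the benefit is strict control of false splits — which is what
the zero-CNA specificity of "average cells" (below) leans on. Significant
splits recurse; segments never shrink below 2 usable bins. Finally,
changepoints are greedily undone while the residual sum of squares stays
within `1 + undo.prune` times that of the full changepoint set.

## Integer copy numbers

Segment mean ratios `r_s` are mapped to integers by a ploidy scale `D`
minimizing the bin-weighted squared distance of `r_s * D` to the nearest
integers over a grid (1.5-5.5, step 0.01, refined at 0.001 and polished
by alternating least squares, which makes the objective exactly zero on
noiseless integer profiles). The objective alone is degenerate — any
multiple of a perfect `D` also fits — so a diploid anchor requires the
bin-weighted modal copy number to be 2; all study subjects are
constitutionally diploid, and a cell whose profile cannot be anchored is
flagged non-callable rather than silently miscalled. Rounding is
half-away-from-zero (2.5 becomes 3), pinned for reproducibility.

CNA events are deviations from the expected copy number: 2 on autosomes;
for males 1 on X and Y; for females 2 on X with Y excluded entirely; with
unknown sex, X/Y events are reported but flagged indeterminate. Adjacent
deviant segments with equal copy number merge before the length filter;
only events strictly longer than 10 Mb of genomic span (masked gaps
included — 10 Mb is a genomic length) are reported.

## Quality control

A cell is excluded when the coefficient of variation of its bin counts is
>= 1 or its total usable reads are <= 3x10^5, both boundaries exclusive of
passing. The read threshold appears in the source material as "3E-5",
which is physically meaningless for a read count; this package reads it
as 3x10^5, the order needed to populate ~2800 bins, and treats that as a
corrected typo. The original pipeline additionally applied a manual
review of CNA profiles whose criteria are not documented; this package
substitutes pinned automated criteria — MAPD above 0.45, more than 40
segments genome-wide, or >30% of the autosomes at non-modal copy number
with no single coherent event >= 10 Mb — exposed as configuration. It is
a stand-in, not a reproduction, so published pass rates that depended on
the manual review (e.g. an overall 73% retention) are deliberately out of
reach. The scRNA-seq filter (>= 300 detected genes, <= 30% mitochondrial
reads, boundaries passing) is provided as a standalone function.

## TE biopsies and mosaic fractions

TE CNV-seq runs the same normalization and segmentation on ~2.5 Mb bins
with a two-round control: round 1 estimates CNAs with depth + GC
normalization only; samples with no events that pass the automated
profile check are pooled (trimmed mean) into a control; round 2
re-normalizes and re-segments everything against it. One refinement on
eligibility: an apparent round-1 event that recurs at the same locus
with the same direction in at least half the batch is the batch-shared
amplification wave, not biology — the same judgment a reviewer applies
when every sample shows the identical "event" — and does not disqualify
a sample from the control pool (reported events always come from round
2). The converse limitation is a batch in which most samples genuinely
share one aneuploidy; that is indistinguishable from bias without
external information. Two details differ
from the single-cell mode, both consequences of the pool being ~5-10
samples rather than ~96 cells: the round-2 control is leave-one-out (a
sample just below the round-1 reporting floor must not suppress its own
signal), and event ratios are taken relative to the bin-weighted median
level of the *other* chromosomes (a whole-chromosome mosaic gain shifts
the renormalized genome mean and would otherwise bias its own estimate).
When the eligible pool is already at its minimum, a sample cannot be
excluded from its own control; its results carry a `self_in_control`
flag because a below-floor mosaic would then suppress roughly `1/pool`
of its own signal. When a batch-wide amplification excursion leaves no
eligible controls at all, round 2 is skipped with a warning and round-1
results are returned.

A reported segment's mosaic fraction inverts the single-copy mixture
mean `ratio(f) = 1 +/- f/2`, i.e. `f = clamp(2|ratio - 1|, 0, 1)`;
`f >= 0.8` is classed as full aneuploidy, `0.2 <= f < 0.8` as mosaic, and
below 0.2 nothing is reported. The 0.2-0.8 band follows common PGT-A
reporting practice; the kit-internal thresholds of any given clinical
assay are not public, so the band is a documented substitute.

## Concordance

Each (cell event, TE event) pair is classified by the overlap fraction
`o` = overlap / length of the smaller event: `no_overlap` at `o = 0`;
`concordant` when `o >= 0.5` and directions match; `direction_discordant`
whenever the directions differ on any overlap — the pattern seen when a
blood cell carries a short deletion inside a region the biopsy reported
as gained; `partial_overlap` otherwise. A cell corresponds to the biopsy
iff any pair is concordant. The >= 50%-of-the-smaller rule with matching
direction is a deliberate operationalization of a judgment the source
analysis applied narratively; it is configurable, and a whole-chromosome
TE event is matched by any same-direction cell event covering at least
half of that chromosome. Per-infant summaries report the fraction of
QC-passing cells with CNAs and the detection floor `1 / n_cells`: with
zero concordant cells among n, blood mosaicism is absent or below that
fraction.

## The synthetic-data generator

The generator is first-class, tested code. A cell's expected count in bin
`b` is

    lambda_b = R * w_b * (cn_b / 2) * g(gc_b) * A_b * P_b

with `R` scaling to the cell's library size (log-normal spread 0.2 around
10^6 usable reads), `w_b` the bin weight, `cn_b` the true copy number
from the cell's karyotype, `g` a smooth GC-efficiency curve,
`A_b` a plate-shared and `P_b` a cell-private exponentiated AR(1)
Gaussian field. Counts are negative binomial with size 20 (Poisson
available as the clean limit). Defaults: shared field sigma 0.25 with
10-bin autocorrelation; private field sigma 0.08 with 2-bin
autocorrelation. The asymmetry is deliberate: the long-range MALBAC
amplification waves are reproducible across cells of a plate — that
reproducibility is the entire premise of the pooled-plate control — so
the wave component belongs to the shared field and what remains private
is near-local amplification stochasticity. The synthetic GC track also
uses a short (2-bin) correlation so GC strata sample all chromosomes; on
a toy genome with few chromosomes, a chromosome-collinear GC track would
let the LOWESS correction absorb true whole-chromosome CNAs, an artifact
of the genome size rather than the method.

TE biopsies are pseudobulk: expectation proportional to the mixture
profile `f * cn_aneu + (1 - f) * 2`, a batch-shared wave of log-sd 0.04,
a private field averaged over the biopsy's 10 cells
(`sigma / sqrt(10)`), and Poisson counts — bulk low-pass libraries start
from many genome copies, so per-bin jackpotting is not the right noise
law there, and the 0.04 bound on the shared wave is implied by the
method's own design: round-1 pooling requires euploid round-1 profiles
to sit below the mosaic reporting floor. "Average cell" mode replaces
every cell's expectation with the plate-mean expectation, emulating
pooled nuclei evenly re-split across a plate — the validation design in
which any CNA call is a false positive.

The default synthetic genome is six autosomes with human-like lengths
(240 down to 80 Mb), a 120 Mb X and a 40 Mb Y at 1 Mb bins (~1060 bins),
with 2% of bins masked. This keeps chromosome-to-event size ratios
realistic while staying ~3x smaller than a real genome for speed.

### What the generator does and does not emulate

It reproduces GC bias, shared-vs-private amplification waves,
overdispersed counts, mosaic cell mixtures within plates, library-size
spread, masked bins, and pseudobulk biopsies at chosen mosaic fractions.
It does not simulate reads at the base level, sequencing error, chimeric
MALBAC artifacts, mappability structure, or real bad-bin geography. Tests
passing on synthetic data therefore demonstrate the statistical
correctness of the pipeline under its stated noise model, not performance
on any particular real library.

## Numerical choices and edge cases

* Coordinates are 0-based half-open internally; scaffold readers accept a
  1-based dialect flag. A read exactly on a bin boundary belongs to the
  bin starting there.
* Bad-bin masking flags a bin at >= 50% overlap of its span with the
  (coalesced) mask; the threshold is symmetric and scale-free.
* Zero-count bins are legal (ratio 0); the log2 offset `eps = 1e-3`
  absorbs them in segmentation.
* A chromosome with fewer than 4 usable bins becomes a single flagged
  segment.
* Ploidy-scale ties break toward `2 / median(ratio)`; all tie-breaks in
  the scan statistic resolve to the smallest indices, so segmentation is
  deterministic bit-for-bit under a fixed seed on one platform.
* Problem sizes in the shipped tests: the synthetic genome above;
  96-cell plates; cohorts of 200 cells per infant; 20-seed replicates
  for stochastic properties. These were chosen as the smallest sizes at
  which chromosome-scale events, plate controls and cohort summaries are
  all exercised at realistic ratios.

## Known limitations

* The real 2808-bin hg19 scaffold and its bad-bin list derive from
  mappability data that are inputs here, not reproduced; fixed-width
  bins stand in for simulation.
* The union-bound tail approximation is conservative; events near the
  10 Mb detection boundary at high noise lose some power relative to a
  sharper scan-statistic approximation.
* The mosaic-fraction estimator assumes a single-copy change; a
  two-copy event at fraction f/2 is indistinguishable from a one-copy
  event at fraction f by mean ratio alone.
* Whether the original control excluded later-found-aneuploid cells, and
  whether GC LOWESS was fit per cell or pooled, are not documented
  upstream; this package fits per cell and does not exclude by default,
  exposing an exclusion list.
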