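---
title: "Methods: genome doubling detection, haploidisation and molecular-clock timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome doubling detection, haploidisation and molecular-clock timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wgdclock)
```

# The model

`wgdclock` analyses tumour genomes described by two observables: an
allele-specific copy-number segmentation (per segment, major and minor
copy numbers `n_maj >= n_min`), and somatic SNVs with alt/total read
counts. All genome fractions are computed over autosomes 1–22 only;
sex chromosomes are excluded from every denominator because their
baseline copy number is sex-dependent and would bias LOH and ploidy
fractions. Coordinates are 1-based inclusive throughout.

## Copy states

Segments are classified by the narrow enumeration used in the
chondrosarcoma literature: `diploid` (1+1), `gain` (2+1 trisomy, 2+2
tetrasomy), `cnLOH` (2+0) and `other` for everything else, so 3+1 or
1+0 deliberately land in `other`. Amplification is total copy number
at least 5 in diploid genomes and at least 9 in genome-doubled ones —
the doubled threshold is (roughly) the diploid one scaled by the
doubling, and the "at least" reading resolves an evident typo in the
source description of the rule.

## Genome doubling

GD is called by clustering a per-sample scalar across the cohort with
a one-dimensional Gaussian mixture fitted by EM, selecting the number
of components (1–3) by BIC. The clustering feature is the
**major-allele ploidy** `psi_maj` (length-weighted mean of `n_maj`),
not total ploidy. The reason is partial haploidisation: a genome that
loses one parental copy of 60% of its autosomes and then doubles is
mostly 2+0, with total ploidy ~2.8 — indistinguishable from diploid on
a total-ploidy axis — but `psi_maj` is ~2, exactly where doubled
genomes sit. The source method names its clustering tool but not its
feature; the feature choice here is this package's own design
decision, made so that HP+GD genomes are detectable, and it is the
single most consequential free choice in the package.

A sample is GD iff its maximum-posterior component has mean
`psi_maj >= 1.6`. The boundary sits between the theoretical diploid
(1.0) and doubled (2.0) values with margin for purity/segmentation
noise and is configurable. Cohorts below 10 samples skip the mixture
(unstable) and threshold each sample's own `psi_maj` at the same
boundary; the method used is recorded per call.

EM numerical choices (the source specifies none): k-means++-style
initial means drawn from the data, 20 restarts, convergence at
log-likelihood improvement < 1e-8, component variances floored at
1e-4 so a degenerate cohort (all values identical) keeps a finite
likelihood and collapses to K = 1 via BIC. BIC counts 3K − 1 free
parameters. All restarts are driven by one seed, so fits are
reproducible.

## Partial haploidisation

HP is a pure threshold: strictly more than 50% of the autosomal
segmented genome with `n_min = 0`. Exactly 50% is *not* HP. The LOH
denominator is the segmented autosomal length (whether the source
included unsegmented gaps is unstated; segmented length is the
reproducible choice).

## Molecular-clock timing of GD

An SNV on `m` of the `n_t` tumour copies at purity `rho` has expected
VAF `f = m rho / (rho n_t + 2 (1 - rho))`. Multiplicity is estimated
by inverting this relation and rounding, clamped to `[1, n_maj]`
(a somatic point mutation sits on one parental haplotype). Hard
rounding rather than a binomial-likelihood soft assignment is a
deliberate simplification, adequate at depth >= 60 where the
multiplicity-1 and -2 VAF clusters are well separated; the
misassignment rate at depth 80, purity 0.8 is a few percent and
roughly symmetric, which the timing-recovery tests bound in effect.

In segments created by the doubling, pre-GD mutations are duplicated
(m = 2) and post-GD mutations are private (m = 1). Counting `n2`
multiplicity-2 and `n1` multiplicity-1 SNVs:

* 2+2 segments: pre-GD accrual on 2 copies, post-GD on 4, so
  `pi = 2 n2 / (2 n2 + n1)`;
* 2+0 segments: pre-GD on the single surviving copy, post-GD on 2 —
  the copy ratio is the same, and the same formula applies;
* 2+1 segments: `pi = 3 n2 / (2 n2 + n1)`, clamped to [0, 1].

2+1 segments are *excluded* from the per-sample aggregate by default:
a single-copy gain need not be synchronous with the doubling, so
folding it in would mix two clocks. They can be included by flag.
The aggregate is the SNV-count-weighted mean of per-segment `pi` over
2+2 and 2+0 segments — all created simultaneously by the one doubling
event — which pools segments approximately by information content.
Uncertainty comes from a seeded bootstrap resampling SNVs within
segments (percentile 95% interval, 200 replicates by default).

Thresholds: segments need >= 10 assigned SNVs to be informative,
samples >= 50 informative SNVs to be timed at all; below that the
result is an explicit "untimeable", never a noisy number.

## Hotspot genotyping

Exact `(chrom, pos, ref, alt)` matching against a versioned GRCh38
table bundling IDH1 R132C/G/H/L/S, IDH2 R172G/K/M/S/W and TERT
promoter C228T (g.1295113) / C250T. The coordinates were curated from
the canonical transcripts because the source's own hotspot list is in
an inaccessible supplement. Samples matching both IDH1 and IDH2 get a
conflict flag and the higher-VAF gene. An override table implements
orthogonal-assay precedence (a later targeted assay supersedes the
sequencing call), mirroring how discordant assays are resolved in
practice. Structural events near the TERT promoter are out of machine
scope; they enter through the override column.

## Cohort statistics

`fisher_exact` computes the two-sided exact test by enumerating all
margin-fixed tables and summing the null probabilities of those no
more probable than the observed table (relative tolerance 1e-7, the
convention of the standard R implementation). Tables with grand total
<= 200 are enumerated (2x2 reduces to the hypergeometric); larger
tables — or pathological many-celled ones that trip a 2e6-table
guard — fall back to seeded Monte-Carlo sampling via Patefield's
algorithm, with the method and seed recorded. `wilcoxon_rank_sum`
enumerates the exact Mann-Whitney null for combined n <= 20 without
ties, and otherwise uses the tie-corrected normal approximation with
continuity correction.

Arm events: an arm is gained/lost if >= 50% of its segmented length
has total copy number above/below the sample's rounded baseline (2,
or 4 when GD). Both the 50% rule and the ploidy-relative baseline are
declared package decisions — the source states no rule — and both are
parameters. Frequency comparisons across groups use Fisher tests with
Bonferroni correction (factor = tests actually performed), following
the source's stated correction choice.

Fragmentation: per chromosome, breakpoints = segments − 1 *after
merging adjacent segments with identical copy state* (so segmentation
dialect cannot inflate counts); a chromosome is "high breakage" at
>= k breakpoints, k = 10 by default. The exact threshold used by the
source is in an inaccessible supplement; k is exposed and documented
as a decision, not a reconstruction. This statistic is a deliberate
simplification standing in for full chromothripsis calling, which is
out of scope.

# The synthetic-data generator

Every inference stage is validated against `simulate_tumour()` /
`simulate_cohort()`, which generate the *stated world* of the tests:

* all autosomes start 1+1; optional HP converts whole chromosomes to
  1+0, in seeded random order, until at least `hp_fraction` of the
  genome is LOH (HP is only generated together with GD, encoding the
  observed co-occurrence);
* at mutational time `gd_time` (on a [0, 1] clock normalised to the
  tumour's whole mutational history) every copy number doubles;
* SNVs accrue on each allele copy at `mu` per Mb per unit time
  (default 0.3, giving a diploid burden of a few thousand SNVs —
  typical of a quiet adult solid tumour); pre-GD mutations end at
  multiplicity 2, post-GD at 1;
* observed VAFs follow the purity-dilution formula; reads are
  Poisson-depth binomial draws, or deterministic
  (`alt = round(depth * f)`) in noise-free mode for exact-inversion
  tests;
* optional late arm gain/loss events (default off) perturb copy
  states *after* mutation accrual — they exist for copy-number-only
  cohort simulations of the arm-level statistics and deliberately do
  not touch the timing-informative segments.

Two modelling notes. First, HP is modelled as whole-chromosome
minor-copy loss — the parsimonious mechanism behind near-haploid
karyotypes. A consequence worth stating: mutations private to the
lost copy vanish with it, so the surviving lineage's clock runs over
the whole pre-GD interval regardless of *when* HP happened. HP timing
is therefore unobservable in this data type, which resolves the open
question of where to place HP: the `hp_time` parameter exists but
cannot, and does not, affect the observables. Second, the generator
emits *true* integer copy-number segments: it emulates Battenberg's
output format, not its errors. Green recovery tests therefore
establish correctness of the inference logic under clean
segmentation, purity dilution and read noise — not robustness to
segmentation error, subclonality (no subclones are simulated), or
purity misestimation.

# Calibration of the arm-level tests

The acceptance suite checks that under a null cohort (two groups of
30, identical arm-event rates) the raw Fisher rejection rate at 0.05
lies within three binomial standard errors of 0.05 over ~200 tests.
An exact analysis (summing binomial table probabilities over all
2x2 outcomes) shows the test's *true* type-I rate in this world is
~0.02–0.03: exact tests on discrete tables are conservative by
construction, so the band is in practice a one-sided guard against
anti-conservative inflation plus a check that the test is not
degenerate. This is a property of exact tests, not of this
implementation, and the band was fixed from that analysis before the
test was first run.

# Known limitations

* GD detection assumes the cohort's `psi_maj` values form separable
  mixture components; heavily subclonal or low-purity segmentations
  blur this.
* Timing assumes a constant mutation rate per copy (clock-like
  accrual) and clonal mutations only; subclonal SNVs bias `pi`
  downwards if present.
* Only one (clonal) copy-number state per segment is accepted;
  Battenberg subclonal fractions must be collapsed upstream.
* The bundled hotspot coordinates target GRCh38; other builds require
  a user-supplied table.
* The fragmentation statistic is a proxy, not a chromothripsis
  caller.
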