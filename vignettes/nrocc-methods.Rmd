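---
title: "Methods: nuclear receptor occupancy analysis with nrocc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclear receptor occupancy analysis with nrocc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrocc)
```

# The problem

Nuclear receptors such as RXR and its dimerization partners (VDR, RAR,
PPARs, LXRs, TR) occupy thousands of genomic regions, and agonist treatment
shifts that occupancy at a subset of binding regions. ChIP-seq gives a
semiquantitative readout of this occupancy: peak intervals, and per-region
read counts whose normalized magnitude (RPKM) tracks relative binding
strength. `nrocc` implements the desk-side half of such a study — everything
downstream of peak calling and read alignment:

* peak-set algebra (reproducible peaks, consensus regions, blacklist and
  chromosome filters),
* RPKM quantification and ligand-versus-control signal-ratio statistics,
* per-region differential occupancy with fold-change classification,
* PWM motif scanning with empirically calibrated score thresholds and
  response-element prevalence,
* TSS-window association of peaks with regulated genes and occupancy-ratio
  clustering,
* paired occupancy-shift comparison between two factors at co-occupied
  regions, and
* a cross-study signal-ratio meta-analysis harness.

Alignment, peak calling, and differential-expression model fitting are out
of scope: the package consumes peak intervals (BED/narrowPeak), per-region
counts or tag positions, and DE summary tables.

# Conventions and containers

All coordinates are 0-based half-open (BED convention); GTF input is
converted at the boundary (forward TSS = `start - 1`, reverse TSS =
`end - 1`). Interval sets are plain data frames of class `interval_set`
with columns `chrom`, `start`, `end`, `name`, `summit`, `score`; the
algebra is backed by `GenomicRanges` internally. "Overlap" means at least
one shared base unless a larger `min_overlap_bp` is requested, matching the
common default of interval-intersection tools.

Consensus regions count support per base by default: a base belongs to the
consensus when at least `min_samples` distinct sample sets cover it (each
set counted once per base), and surviving bases are merged. The
alternative reading — merge the union, then keep merged regions touched by
at least `min_samples` sets — is available as `mode = "region"`. The two
differ only for chains of partially overlapping regions; the per-base rule
was chosen as the default because it has an unambiguous brute-force
definition that our property tests verify exactly. With a single sample
the merged sample itself is the consensus (the single-replicate rule).

Reproducible peaks default to the interval-tool idiom: records of
replicate 1 that overlap replicate 2, then merged, so reported coordinates
derive from replicate 1. The covered-base symmetric variant is behind
`mode = "covered"`.

# Signal and ratios

RPKM is the closed form `count / ((len/1000) * (depth/1e6))`. The
study-level **signal ratio** compares ligand-stimulated to control
occupancy after averaging replicates within conditions. Two readings of
"the median values and the ratio" exist and both are implemented:

* `ratio_of_medians` (default): `median(treated) / median(control)`,
* `median_of_ratios`: median of per-region ratios.

The choice is recorded in the returned object. Per-region ratios use a
symmetric pseudocount of 0.1 RPKM (configurable) to stabilize
low-signal regions; the global ratio of medians uses none unless the
control median is zero. Even-length medians are the mean of the central
order statistics.

Tags are single-end positions; no fragment extension or shifting is
applied. Summit windows (`±750` bp and `±1000` bp presets) are truncated
at position 0 and RPKM uses the realized window length. Binned
read-distribution matrices conserve window totals exactly in either counts
or counts-per-million units; the heatmap transform "normalized to the
median" divides each sample column by its median.

# Differential occupancy

The classification thresholds are the primary surface and are exact:
fold change above 1.5 is induced, below 0.66 reduced, with strict
inequalities; the FDR gate is 0.05. The fold-change-only ("exploratory")
and FC + FDR classifications are both computed, and FC-passing regions are
split into `fc_pass_significant` (FDR < 0.05) and `fc_pass_nonsignificant`
(FDR ≥ 0.05).

The per-region test is an in-package negative-binomial exact-style test;
numerical parity with external differential-binding tools is deliberately
not claimed. Counts are scaled to the mean library size, summed within
conditions, and the split of the two sums is tested conditionally on their
total under NB sampling, accumulating the probability of all outcomes no
more likely than the observed one (two-sided). Dispersion is
parameterized as variance `mu + alpha * mu^2` and estimated by method of
moments:

* the **common** dispersion is the debiased ratio-of-sums estimator
  `sum(v - m) / sum(m^2 - bias)` across regions, where the denominator
  corrects for `E[m^2] = mu^2 + (mu + alpha mu^2)/n`. A median of
  per-region moment ratios is badly biased downward at 1–2 residual
  degrees of freedom and made the test visibly liberal in null
  simulations; the debiased pooled estimator restores size.
* **tagwise** values shrink each region's (debiased, floored at 0) moment
  ratio toward the common value with `prior_df = 20` pseudo-degrees of
  freedom. The default was set by null-calibration simulation at the
  package's reference conditions (NB mean 200, dispersion 0.05, two
  replicates per condition): observed type-I error 0.051 on average
  (range 0.035–0.066 across 20 simulated studies of 1000 regions).
* dispersions are floored at `1e-4` to avoid degenerate Poisson fits.

All-zero regions receive `p = 1` by convention and are flagged.
Benjamini–Hochberg adjustment runs over all tested regions with no
independent filtering. The FC pseudocount defaults to 0.5 counts.

A consequence worth knowing: with two replicates at these noise levels the
FC-only rule mislabels roughly 8–9% of truly unresponsive regions as
responsive — that is the price of the exploratory rule, not an
implementation artifact. Specificity for the unresponsive class is
therefore a property of the FDR-gated classification (where it exceeds
0.98 in our recovery simulations), while the FC-only rule is assessed by
its sensitivity.

# Motif analysis

PWMs are width × 4 probability matrices (A, C, G, T); HOMER `.motif`
probability rows and JASPAR PFM count rows are both read, counts converted
with a pseudocount of 0.25 per cell. Scores are base-2 log odds against a
uniform background by default (a genome-composition background is
selectable and recorded in the threshold object). Windows containing `N`
are skipped rather than scored.

Threshold calibration mirrors empirical-FPR practice: sample `n = 5000`
background sequences from the allowed chromosomes, size-matched by drawing
lengths with replacement from the query set's length distribution; a
sequence is a *positive match* when its best window score over both
strands reaches the cutoff; the cutoff is the smallest observed best score
keeping the positive fraction at or below the 5% target (the empirical
upper quantile, ties resolved toward the smaller positive fraction).
Window-level calibration is available as an alternative mode. A PWM whose
best-score distribution cannot reach the target (all scores tied) is
reported as non-calibratable rather than silently truncated.

The bundled `dr_pwm()` builds DR0–DR5 direct repeats of the AGGTCA half
site (DR3 being the canonical VDR-RXR element). The consensus probability
varies along the half site and the off-base remainder is split 3:2:1 in a
position-rotated order. This matters: with a uniform consensus
probability every window score collapses onto a handful of match-count
levels, the best-score distribution becomes heavily tied, and a 5%
empirical quantile is unattainable; the varied profile behaves like real
receptor PWMs, whose scores are nearly continuous.

Prevalence is the fraction of peaks containing at least one hit (≥ 1 bp
overlap). When motif instances are planted as exact consensus copies (see
the generator below), background sequences sampled from the *planted*
genome contain identical top-scoring copies in a few percent of control
sequences at the default 10 Mb scale. The calibrated cutoff then reflects
the genome as it is — motifs included — exactly as real-genome calibration
does, at the cost of a conservative shift of the cutoff. At very small toy
scales the contamination can exceed the 5% target itself, making the
empirical quantile unattainable (every candidate cutoff admits too many
tied top scores); there the calibration background should be drawn from
the motif-free genome.

# Genes, windows, clusters

Upregulated genes are selected with strict thresholds FC > 1.5 and
FDR < 0.05 from a supplied DE table, optionally intersected with a
protein-coding list. One TSS per gene is used — the annotated gene-level
feature's 5′ end — since gene-level windows are the unit of association.
Peaks map to every gene whose `TSS ± 25 kb` window (inclusive both ends,
clipped at zero) they overlap; there is no nearest-gene tie-breaking, so
the map is many-to-many. Genes without peaks are reported separately, not
silently dropped.

Gene-level occupancy sums the (replicate-averaged) signal of mapped peaks
per condition; the ratio `R = (sum_a + pc) / (sum_b + pc)` is binned into
five clusters with boundaries closed exactly as printed:
c1 `R ≤ 0.66`, c2 `0.66 < R ≤ 0.8`, c3 `0.8 < R ≤ 1.25`,
c4 `1.25 < R ≤ 1.5`, c5 `R > 1.5`.

Peak-feature correlations default to Spearman — the ratio distributions
are heavy-tailed, and rank correlation is the safer default when the
coefficient is not otherwise specified — with Pearson selectable; the
choice is recorded in the output. The gene-subset intersection
("mRNA at least 1.5-fold lower" and "occupancy at least 1.25-fold lower")
uses non-strict boundaries, reading "at least" inclusively; strict
variants are a flag away.

# Paired occupancy shift

At regions co-occupied by two factors, per-region ligand/control ratios
are paired and the "systematic shift" toward one factor is made testable
as:

* `delta = median(log2 ratio_a - log2 ratio_b)`,
* a two-sided exact sign test on the paired differences (ties excluded,
  the standard exact procedure), and
* the fraction of regions strictly above the diagonal.

The statistic is a package addition (the phenomenon is usually shown
graphically) and is labeled as such in outputs; a Wilcoxon signed-rank
alternative is provided. Cross-study summaries use the arithmetic mean of
per-region ratios per factor by default ("average signal ratio" read
literally); the geometric mean is selectable because log-scale averaging
is a defensible alternative reading.

# Meta-analysis harness

Study inclusion is declarative over a local manifest — no network
retrieval: both conditions present, treatment duration ≤ 24 h, published,
at least 2000 consensus regions, and at most 10 studies per receptor with
replicate-rich studies preferred, then the most recent, with study id as
the deterministic tie-break. The per-study ratio composes the published
stage operations exactly: consensus regions → RPKM → replicate averages →
medians → ratio (a property test asserts the composition equals the
pipeline result). Receptor summaries report the median across studies,
flagged when only one study backs the value.

# The synthetic-data generator

The generator defines the study conditions under which the package is
validated; its defaults are fixed and are not tuned per test:

* genome: two 5 Mb chromosomes (`NC_T1`, `NC_T2`) at GC 0.45, plus a
  50 kb decoy scaffold (`NW_T1`) that chromosome filters must remove;
* peaks: 5000 non-overlapping intervals of 200–800 bp laid out slot-wise,
  summits near the center; 80% unresponsive (FC 1), 10% induced (FC 3),
  10% reduced (FC 1/3);
* counts: negative binomial with mean 200 and dispersion 0.05
  (`var = mu + 0.05 mu^2`; dispersion 0 degenerates to Poisson), two
  replicates per condition, library sizes around 20 million reads whose
  ±10% spread exercises depth normalization;
* motifs: the DR3-type consensus planted into 70% of induced peaks and 5%
  of other peaks, random strand, coordinates recorded;
* genes: 400 genes, 15% upregulated (DE FC > 1.5 and FDR < 0.05 by
  construction), 95% of upregulated genes placed with an induced peak
  summit within 25 kb of the TSS.

Peak-class fractions, fold changes, and NB parameters match the reference
conditions of the differential-recovery validation; sample sizes
(2 replicates, ~20 M reads) are typical of the ChIP-seq studies the
pipeline targets. Every artifact draws from a named substream of the
master seed (`substream_seed`), so regeneration is byte-identical
piecewise and end-to-end — the determinism the pipeline's provenance
records rely on.

What the generator does *not* emulate: mappability and accessibility
biases, fragment-length effects, correlated peak widths and signal
strengths, motif instances weaker than consensus, and overdispersion
heterogeneity across regions. Passing recovery tests on this synthetic
truth therefore demonstrates correctness of the computations and
calibration of the statistics under the stated model — not performance on
real libraries.

# Problem sizes and numerical choices

The validation suite runs at deliberately chosen scales: interval-algebra
properties on ~1000 random instances over ≤ 10 kb toy chromosomes;
threshold-calibration transfer on the default 10 Mb genome with two
independent 5000-sequence backgrounds; differential recovery on three
generated 5000-peak studies (stochastic recovery metrics are averaged over
the three to damp the seed-to-seed fluctuation of the realized
false-discovery proportion, whose standard deviation is about 0.01 per
study); null calibration over 20 simulated 1000-region studies; prevalence
recovery over 20 small planted genomes; shift recovery over 20 studies of
1000 paired regions plus 1000 null datasets for the sign test's size; and
one full pipeline run executed twice and compared file-by-file by
checksum.

Tie-breaks and degenerate inputs are handled deterministically
throughout: stable (chrom, start, end) sorting; strict threshold
inequalities exactly as printed; quantile ties resolved toward the smaller
positive fraction; sign-test ties excluded; all-zero regions flagged with
`p = 1`; zero-variance features flagged as undefined rather than silently
dropped.

# Known limitations

* The NB exact-style test is calibrated for the package's reference
  conditions; designs with covariates, batch effects, or strongly
  region-dependent dispersion need a GLM-based tool instead.
* Motif planting writes exact consensus copies; prevalence contrasts are
  therefore sharper than with naturally degenerate instances.
* The meta-analysis harness trusts the manifest; it does not parse
  repository metadata or retrieve data.
* `DiffBind`-style summit re-centering before counting is not applied;
  regions are quantified as provided.
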