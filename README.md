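# nrocc — nuclear receptor occupancy analysis

`nrocc` analyses ligand-induced changes in nuclear-receptor chromatin
occupancy from ChIP-seq peak intervals and per-region read counts. It is
aimed at regulatory-genomics analysts who already have peaks (BED/narrowPeak)
and counts (or tag positions) for control and ligand-treated samples and
want the downstream statistics: which peaks respond to ligand, whether the
factor's response elements are enriched in the responsive peaks, which
regulated genes those peaks sit next to, and how one factor's occupancy
shift compares with its dimerization partner's — within one study or across
many.

## What it computes

**Peak algebra.** Reproducible peaks (detected in both replicates),
consensus regions (bases supported by ≥ *k* sample sets, merged), ENCODE
blacklist and chromosome-name filtering, overlap fractions — all on 0-based
half-open (BED) coordinates.

**Occupancy and signal ratios.** RPKM per region,
`count / ((len/1000) · (depth/10⁶))`; replicate averaging; the study-level
signal ratio `median(treated) / median(control)` (ratio of medians, with
median-of-ratios as an alternative); per-region ratios with a symmetric
pseudocount.

**Differential occupancy.** A negative-binomial exact-style test per region
(variance `μ + αμ²`, moments-based common dispersion debiased by a
ratio-of-sums estimator, tagwise shrinkage, conditional two-sided test on
the condition sums) with Benjamini–Hochberg FDR; classification with
strict thresholds — induced `FC > 1.5`, reduced `FC < 0.66`, FDR gate
`0.05` — in both fold-change-only ("exploratory") and FC + FDR modes, plus
the FC-pass significant/non-significant split.

**Motifs.** HOMER/JASPAR PWM input, base-2 log-odds scanning of both
strands, score thresholds calibrated so that 5% of `n = 5000` size-matched
random background sequences score as positive matches, genome-wide hit
tables, per-peak-set prevalence, and per-peak best scores (e.g. DR3, the
canonical VDR-RXR direct repeat, built in via `dr_pwm(3)`).

**Genes.** Upregulated-gene selection (`FC > 1.5`, `FDR < 0.05`, coding
list), peak-to-gene mapping in TSS ± 25 kb windows, summed gene-level
occupancy ratios `R` with the five-cluster binning
(c1 `R ≤ 0.66` … c5 `R > 1.5`), peak-feature correlations, and gene-subset
intersections (mRNA ≥ 1.5-fold down ∩ occupancy ≥ 1.25-fold down).

**Shift and meta-analysis.** Paired per-region ratios for two factors at
co-occupied regions with a median-log2-difference + exact sign-test shift
statistic; manifest-driven study filtering (≤ 24 h treatment, ≥ 2000
consensus regions, ≤ 10 studies per receptor) and per-receptor median
ratios.

**Synthetic studies.** A fully seeded generator (genome, classed peaks,
NB counts, planted DR motifs, linked genes/expression, ground-truth
manifest) so the whole pipeline runs and validates with no external data.

## Worked example

A complete synthetic study at the default scale (two 5 Mb chromosomes,
5000 peaks, 2 × 2 samples), analysed end to end:

```r
library(nrocc)

study <- simulate_study(seed = 42)
peaks <- filter_regions(study$peaks, allowed_chrom_pattern = "NC")
idx   <- match(peaks$name, rownames(study$counts))

sm <- rpkm_matrix(peaks, counts = study$counts[idx, ], samples = study$samples)
signal_ratio(sm, "ligand", "vehicle")
#> signal ratio (ligand vs vehicle): 0.9953 [ratio_of_medians; medians 19.7572 / 19.8505; n = 5000]
```

Global occupancy barely moves (the generator plants balanced induced and
reduced classes), which is exactly why per-region classification matters:

```r
ct <- count_table(peaks, study$samples, study$counts[idx, ])
d  <- diff_occupancy(ct, "ligand", "vehicle")
table(exploratory = d$class_fc_only, fc_fdr = d$class_fc_fdr)
#>               fc_fdr
#> exploratory    induced reduced unresponsive
#>   induced          514       0          131
#>   reduced            0     503          143
#>   unresponsive       0       0         3709
```

The exploratory (FC-only) sets recover the planted 500 + 500 responsive
peaks, and the FDR gate trims the borderline calls. Motif analysis on the
same study — threshold calibrated at a 5% empirical FPR, then genome-wide
scanning:

```r
bg  <- sample_background(study$genome, peaks$end - peaks$start, n = 5000,
                         seed = substream_seed(42, "background"))
thr <- calibrate_threshold(study$pwm, bg, target_fpr = 0.05)
thr
#> score_threshold for DR3: cutoff 11.8389 (target FPR 0.050, achieved 0.0500, n = 5000, sequence-level)

hits <- scan_motif(study$genome, study$pwm, thr)
ind <- peaks[peaks$name %in% d$region[d$class_fc_only == "induced"], ]
unr <- peaks[peaks$name %in% d$region[d$class_fc_only == "unresponsive"], ]
sprintf("DR3 prevalence: induced %.1f%%, unresponsive %.1f%%",
        100 * motif_prevalence(ind, hits), 100 * motif_prevalence(unr, hits))
#> [1] "DR3 prevalence: induced 55.3%, unresponsive 8.0%"
```

The planted response element is several-fold enriched in ligand-induced
peaks over unresponsive ones — the qualitative contrast the classification
is meant to expose. Finally, peak-to-gene association and occupancy-ratio
clustering for the upregulated genes:

```r
up   <- select_upregulated(study$de)
gmap <- map_peaks_to_genes(peaks, study$genes[study$genes$gene_id %in% up$gene_id, ])
gocc <- gene_occupancy_ratio(gmap, sm, "ligand", "vehicle")
table(gocc$cluster)
#> c1 c2 c3 c4 c5
#>  0  0 39 18  3
```

`run_pipeline(default_config(seed = 1), "out_dir")` executes all of the
above in dependency order, writes every table as TSV/BED/JSON with a
provenance record, and reruns byte-identically under the same
configuration. A thin command-line wrapper with `simulate`, `run` and
`validate` subcommands is installed at `inst/scripts/nrocc`.

## Method sources

The methods vignette (`vignettes/nrocc-methods.Rmd`) documents the models,
the calibration of the NB test, every tunable threshold with its default,
what the synthetic generator does and does not emulate, and the package's
numerical conventions.
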