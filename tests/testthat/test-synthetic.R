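small_lengths <- c(NC_T1 = 2e5, NC_T2 = 2e5, NW_T1 = 2e4)

test_that("genome generation is seeded and composition-faithful", {
  g1 <- sim_genome(small_lengths, gc = 0.5, seed = 11)
  g2 <- sim_genome(small_lengths, gc = 0.5, seed = 11)
  expect_identical(g1, g2)
  g3 <- sim_genome(small_lengths, gc = 0.5, seed = 12)
  expect_false(identical(g1, g3))
  expect_equal(unname(nchar(g1)), unname(small_lengths))

  n <- sum(nchar(g1))
  gc_obs <- sum(vapply(g1, function(s)
    lengths(regmatches(s, gregexpr("[GC]", s))), 1)) / n
  expect_lt(abs(gc_obs - 0.5), 3 * sqrt(0.25 / n))

  f <- tempfile(fileext = ".fa")
  write_genome(g1, f)
  expect_equal(read_chrom_sizes(paste0(f, ".sizes")),
               stats::setNames(as.numeric(small_lengths),
                               names(small_lengths)))
  back <- Biostrings::readDNAStringSet(f)
  expect_equal(as.character(back[["NC_T1"]]), g1[["NC_T1"]])
})

test_that("peaks are non-overlapping with class fractions as stated", {
  pk <- sim_peaks(small_lengths, n_peaks = 300, seed = 21, n_decoy = 10)
  expect_equal(nrow(pk$peaks), 310)
  expect_equal(sum(!pk$truth$decoy), 300)
  expect_equal(as.integer(table(pk$truth$class[!pk$truth$decoy])[
    c("induced", "reduced", "unresponsive")]), c(30, 30, 240))
  # non-overlap within each chromosome
  for (ch in unique(pk$peaks$chrom)) {
    p <- pk$peaks[pk$peaks$chrom == ch, ]
    expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
  }
  expect_true(all(pk$peaks$summit >= pk$peaks$start &
                  pk$peaks$summit < pk$peaks$end))
  # the decoy scaffold peaks vanish under the NC filter
  kept <- filter_regions(pk$peaks, allowed_chrom_pattern = "NC")
  expect_equal(nrow(kept), 300)
  expect_error(sim_peaks(small_lengths, class_fractions = c(a = 0.5, b = 0.4)),
               "sum to 1")
})

test_that("counts follow the NB model with planted fold changes", {
  pk <- sim_peaks(small_lengths, n_peaks = 400, seed = 31, n_decoy = 0)
  cnt <- sim_counts(pk$truth, nb_mean = 200, nb_dispersion = 0.05,
                    library_sizes = rep(2e7, 4), seed = 31)
  expect_equal(dim(cnt$counts), c(400, 4))
  unresp <- pk$truth$class == "unresponsive"
  # moment check: empirical mean within 3 sigma of the NB mean
  m <- mean(cnt$counts[unresp, 1:2])
  se <- sqrt((200 + 0.05 * 200^2) / (2 * sum(unresp)))
  expect_lt(abs(m - 200), 3 * se)
  ind <- pk$truth$class == "induced"
  m_tr <- mean(cnt$counts[ind, 3:4])
  se_tr <- sqrt((600 + 0.05 * 600^2) / (2 * sum(ind)))
  expect_lt(abs(m_tr - 600), 3 * se_tr)

  # dispersion 0 degenerates to Poisson (variance ~ mean)
  cnt0 <- sim_counts(pk$truth, nb_mean = 100, nb_dispersion = 0,
                     library_sizes = rep(2e7, 4), seed = 32)
  v <- var(as.numeric(cnt0$counts[unresp, 1]))
  expect_lt(abs(v / 100 - 1), 0.25)

  # library sizes scale the means
  cnt2 <- sim_counts(pk$truth, nb_mean = 200, nb_dispersion = 0.05,
                     library_sizes = c(4e7, 1e7, 2e7, 2e7), seed = 33)
  expect_gt(mean(cnt2$counts[unresp, 1]), mean(cnt2$counts[unresp, 2]) * 2)
})

test_that("planted motifs are recorded and recoverable by scanning", {
  g <- sim_genome(small_lengths, seed = 41)
  pk <- sim_peaks(small_lengths, n_peaks = 200, seed = 41, n_decoy = 0)
  x <- dr_pwm(3)
  pl <- plant_motifs(g, pwm_consensus(x), pk$peaks, pk$truth,
                     rate_in_class = 1, background_rate = 0, seed = 41)
  ind <- pk$truth$name[pk$truth$class == "induced"]
  expect_setequal(pl$planted$name, ind)   # rate 1: every induced peak

  # every planted instance is inside its peak and spelled exactly
  for (i in seq_len(nrow(pl$planted))) {
    row <- pl$planted[i, ]
    spelled <- substr(pl$genome[[row$chrom]], row$start + 1, row$end)
    want <- if (row$strand == "+") pwm_consensus(x) else
      chartr("ACGT", "TGCA", paste(rev(strsplit(pwm_consensus(x), "")[[1]]),
                                   collapse = ""))
    expect_identical(spelled, want)
  }

  # the scanner finds every plant at a calibrated threshold
  bg <- sample_background(pl$genome, pk$peaks$end - pk$peaks$start, n = 300,
                          seed = 42)
  thr <- calibrate_threshold(x, bg, 0.05)
  hits <- scan_motif(pl$genome, x, thr)
  found <- paste(hits$chrom, hits$start)
  expect_true(all(paste(pl$planted$chrom, pl$planted$start) %in% found))

  # rate 0 plants nothing
  pl0 <- plant_motifs(g, pwm_consensus(x), pk$peaks, pk$truth,
                      rate_in_class = 0, background_rate = 0, seed = 43)
  expect_equal(nrow(pl0$planted), 0)
  expect_identical(pl0$genome, g)
})

test_that("gene layer links upregulated genes to induced peaks", {
  pk <- sim_peaks(small_lengths, n_peaks = 60, seed = 51, n_decoy = 0,
                  width_range = c(200, 500))
  gn <- sim_genes(pk$peaks, pk$truth, small_lengths, n_genes = 80,
                  frac_upregulated = 0.2, frac_linked = 1, seed = 51)
  up <- select_upregulated(gn$de)
  expect_equal(sort(up$gene_id), sort(gn$truth$gene_id[gn$truth$upregulated]))
  expect_equal(nrow(up), 16)

  # every linked gene indeed has its induced peak within the window
  mp <- map_peaks_to_genes(pk$peaks, gn$genes[gn$genes$gene_id %in% up$gene_id, ],
                           half_width_bp = 25000)
  linked <- gn$truth[gn$truth$upregulated & !is.na(gn$truth$linked_peak), ]
  for (i in seq_len(nrow(linked))) {
    expect_true(linked$linked_peak[i] %in%
                  mp$map$peak[mp$map$gene_id == linked$gene_id[i]])
  }

  # directional sanity at sparse peak density: upregulated genes are more
  # often near induced peaks than background genes are
  ind_peaks <- iset_subset(pk$peaks, pk$truth$name[pk$truth$class == "induced"])
  frac_near <- function(ids) {
    g <- gn$genes[gn$genes$gene_id %in% ids, ]
    m <- map_peaks_to_genes(ind_peaks, g, half_width_bp = 25000)
    1 - length(m$genes_without_peaks) / nrow(g)
  }
  expect_gt(frac_near(gn$truth$gene_id[gn$truth$upregulated]),
            frac_near(gn$truth$gene_id[!gn$truth$upregulated]))

  gn0 <- sim_genes(pk$peaks, pk$truth, small_lengths, n_genes = 40,
                   frac_upregulated = 0, seed = 52)
  expect_equal(nrow(select_upregulated(gn0$de)), 0)
})

test_that("a full study bundle regenerates byte-identically from its seed", {
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  st1 <- simulate_study(seed = 61, dir = d1, chrom_lengths = small_lengths,
                        n_peaks = 150, n_genes = 40, background_rate = 0.05)
  st2 <- simulate_study(seed = 61, dir = d2, chrom_lengths = small_lengths,
                        n_peaks = 150, n_genes = 40, background_rate = 0.05)
  for (f in names(st1$files)) {
    expect_identical(readLines(st1$files[[f]]), readLines(st2$files[[f]]),
                     label = paste("file", f))
  }
  expect_identical(st1$counts, st2$counts)
  # truth fractions sum to one over the non-decoy peaks
  real <- st1$truth$peaks[!st1$truth$peaks$decoy, ]
  expect_equal(sum(table(real$class)), 150)
  # written bundle passes validation
  expect_equal(nrow(validate_inputs(d1)), 0)
})
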