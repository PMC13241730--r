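test_that("extract_tss converts GTF coordinates strand-aware", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "gene", "1000", "2000", ".", "+", ".",
          'gene_id "g1"; gene_name "ALPHA"; gene_biotype "protein_coding";',
          sep = "\t"),
    paste("chr1", "src", "gene", "1000", "2000", ".", "-", ".",
          'gene_id "g2"; gene_name "BETA"; gene_biotype "protein_coding";',
          sep = "\t"),
    paste("chr2", "src", "gene", "500", "800", ".", "+", ".",
          'gene_id "g3"; gene_name "GAMMA"; gene_biotype "lncRNA";',
          sep = "\t"),
    paste("chr2", "src", "gene", "10", "90", ".", "-", ".",
          'gene_id "g4"; gene_name "DELTA"; gene_biotype "protein_coding";',
          sep = "\t"),
    paste("chr2", "src", "exon", "500", "600", ".", "+", ".",
          'gene_id "g3";', sep = "\t"),
    paste("chr3", "src", "gene", "1", "50", ".", "+", ".",
          'gene_id "g5"; gene_name "EPS"; gene_biotype "protein_coding";',
          sep = "\t")), gtf)
  tss <- extract_tss(gtf)
  tss <- tss[order(tss$gene_id), ]
  expect_equal(tss$gene_id, paste0("g", 1:5))
  # forward gene 1000-2000 (1-based) -> 0-based TSS 999; reverse -> 1999
  expect_equal(tss$tss, c(999, 1999, 499, 89, 0))
  expect_equal(tss$symbol, c("ALPHA", "BETA", "GAMMA", "DELTA", "EPS"))
  expect_equal(tss$biotype[3], "lncRNA")
})

test_that("select_upregulated applies strict cutoffs and the coding list", {
  de <- data.frame(gene_id = paste0("g", 1:6),
                   fc = c(1.6, 1.5, 2.0, 2.0, 0.5, 3.0),
                   fdr = c(0.01, 0.01, 0.05, 0.001, 0.001, 0.049))
  up <- select_upregulated(de)
  expect_equal(up$gene_id, c("g1", "g4", "g6"))   # g2 FC==1.5, g3 FDR==0.05 out
  up2 <- select_upregulated(de, coding_list = c("g1", "g6"))
  expect_equal(up2$gene_id, c("g1", "g6"))
  expect_error(select_upregulated(de[, 1:2]), "columns")

  set.seed(14)
  big <- data.frame(gene_id = seq_len(500),
                    fc = exp(rnorm(500, 0.3, 0.5)),
                    fdr = runif(500))
  expect_equal(nrow(select_upregulated(big)),
               sum(big$fc > 1.5 & big$fdr < 0.05))
})

test_that("peak-to-gene mapping uses the inclusive TSS window", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
                      tss = c(50000, 200000))
  peaks <- interval_set(rep("chr1", 3),
                        c(50000, 80000, 176000),
                        c(50001, 80500, 176200),
                        name = c("at_tss", "far", "edge"))
  got <- map_peaks_to_genes(peaks, genes, half_width_bp = 25000)
  expect_equal(got$map$peak[got$map$gene_id == "gA"], "at_tss")
  # peak 30 kb from gA is unmapped; peak touching gB's window edge maps
  expect_equal(got$map$peak[got$map$gene_id == "gB"], "edge")
  g2 <- map_peaks_to_genes(peaks, rbind(genes,
                                        data.frame(gene_id = "gC",
                                                   chrom = "chr2", tss = 100)),
                           half_width_bp = 25000)
  expect_equal(g2$genes_without_peaks, "gC")
})

test_that("mapping matches a window-overlap oracle and is input-order stable", {
  set.seed(19)
  for (i in 1:10) {
    peaks <- random_iset(25, "chr1", 3e5, max_width = 800)
    genes <- data.frame(gene_id = paste0("g", 1:8), chrom = "chr1",
                        tss = sample.int(3e5, 8) - 1)
    hw <- 20000
    got <- map_peaks_to_genes(peaks, genes, hw)$map
    oracle <- do.call(rbind, lapply(seq_len(8), function(j) {
      w0 <- max(genes$tss[j] - hw, 0); w1 <- genes$tss[j] + hw + 1
      hit <- peaks$start < w1 & peaks$end > w0
      if (!any(hit)) return(NULL)
      data.frame(gene_id = genes$gene_id[j], peak = peaks$name[hit])
    }))
    oracle <- oracle[order(oracle$gene_id, oracle$peak), ]
    rownames(oracle) <- NULL
    expect_equal(got, oracle)
    shuf <- peaks[sample(nrow(peaks)), ]
    class(shuf) <- c("interval_set", "data.frame")
    expect_equal(map_peaks_to_genes(shuf, genes, hw)$map, got)
  }
})

occ_sheet <- function() {
  data.frame(sample_id = c("a", "b"), condition = c("combined", "single"),
             replicate = 1L, library_size = 1e6)
}

test_that("gene occupancy ratio sums mapped peak signal", {
  reg <- interval_set("chr1", c(0, 1000, 2000), c(500, 1500, 2500),
                      name = c("p1", "p2", "p3"))
  sm <- signal_matrix(reg, occ_sheet(), cbind(c(10, 20, 4), c(5, 10, 4)))
  map <- data.frame(gene_id = c("g1", "g1", "g2"),
                    peak = c("p1", "p2", "p3"))
  occ <- gene_occupancy_ratio(map, sm, "combined", "single", pseudocount = 0)
  expect_equal(occ$ratio_R, c(2, 1))       # (10+20)/(5+10) and 4/4
  expect_equal(as.character(occ$cluster), c("c5", "c3"))

  # splitting one peak's signal into two colocated peaks preserves R
  reg2 <- interval_set("chr1", c(0, 0, 1000, 2000), c(500, 500, 1500, 2500),
                       name = c("p1a", "p1b", "p2", "p3"))
  sm2 <- signal_matrix(reg2, occ_sheet(),
                       cbind(c(4, 6, 20, 4), c(2, 3, 10, 4)))
  map2 <- data.frame(gene_id = c("g1", "g1", "g1", "g2"),
                     peak = c("p1a", "p1b", "p2", "p3"))
  occ2 <- gene_occupancy_ratio(map2, sm2, "combined", "single", pseudocount = 0)
  expect_equal(occ2$ratio_R, occ$ratio_R)
  expect_error(
    gene_occupancy_ratio(data.frame(gene_id = "g", peak = "nope"), sm,
                         "combined", "single"), "missing")
})

test_that("ratio clusters partition exactly at the printed boundaries", {
  expect_equal(as.character(cluster_by_ratio(c(0.66, 0.8, 1.0, 1.25, 1.5,
                                               1.5001, 0.1, 100))),
               c("c1", "c2", "c3", "c3", "c4", "c5", "c1", "c5"))
  expect_error(cluster_by_ratio(0), "> 0")
  expect_error(cluster_by_ratio(-1), "> 0")

  set.seed(27)
  R <- exp(runif(10000, log(0.01), log(100)))
  cl <- cluster_by_ratio(R)
  expect_false(anyNA(cl))
  expect_equal(sum(cl == "c1"), sum(R <= 0.66))
  expect_equal(sum(cl == "c2"), sum(R > 0.66 & R <= 0.8))
  expect_equal(sum(cl == "c3"), sum(R > 0.8 & R <= 1.25))
  expect_equal(sum(cl == "c4"), sum(R > 1.25 & R <= 1.5))
  expect_equal(sum(cl == "c5"), sum(R > 1.5))
})

test_that("feature correlations recover identity, nulls and hand values", {
  set.seed(33)
  r <- exp(rnorm(300, 0, 0.4))
  tab <- peak_feature_correlation(r, list(self = r))
  expect_equal(tab$estimate, 1)

  nulls <- vapply(1:20, function(s) {
    set.seed(700 + s)
    peak_feature_correlation(r, list(perm = sample(r)))$estimate
  }, numeric(1))
  expect_gte(mean(abs(nulls) < 0.12), 0.95)

  # textbook Spearman on a small vector: rho = 1 - 6*sum(d^2)/(n(n^2-1))
  x <- c(3.1, 1.2, 5.4, 2.2, 4.9)
  y <- c(2.0, 1.1, 4.8, 3.0, 4.0)
  d <- rank(x) - rank(y)
  rho_hand <- 1 - 6 * sum(d^2) / (5 * 24)
  expect_equal(peak_feature_correlation(x, list(f = y))$estimate, rho_hand)

  expect_warning(z <- peak_feature_correlation(r, list(const = rep(2, 300))),
                 "zero variance")
  expect_true(is.na(z$estimate))
  expect_equal(peak_feature_correlation(x, list(f = y),
                                        method = "pearson")$estimate,
               cor(x, y))
})

test_that("gene-subset intersection counts reductions with inclusive bounds", {
  expect_equal(intersect_gene_subsets(paste0("g", 1:4), rep(1, 4),
                                      rep(1, 4))$common, character(0))
  genes <- paste0("g", 1:10)
  mrna <- c(0.5, 0.6, 1 / 1.5, 0.9, 1.0, 1.2, 0.2, 1.1, 0.7, 1.0)
  occ <- c(0.7, 0.9, 0.5, 0.8, 1.0, 0.3, 1 / 1.25, 1.2, 1.3, 0.6)
  got <- intersect_gene_subsets(genes, mrna, occ)
  expect_setequal(got$subset_mrna, c("g1", "g2", "g3", "g7"))   # <= 1/1.5
  expect_setequal(got$subset_occupancy, c("g1", "g3", "g4", "g6", "g7", "g10"))
  expect_setequal(got$common, c("g1", "g3", "g7"))
  expect_equal(unname(got$counts), c(4, 6, 3, 10))
  expect_equal(unname(got$fractions), c(0.4, 0.6, 0.3))
  strict <- intersect_gene_subsets(genes, mrna, occ, strict = TRUE)
  expect_false("g3" %in% strict$subset_mrna)   # boundary value drops
})
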